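# Synthetic-data generators: a stated world for exercising the pipeline at
# desk scale.  Every generator is a pure function of (arguments, seed).

# largest-remainder (Hamilton) apportionment of n items to fractions
allocate_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0L) {
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Generate an ordered tiling-probe layout
#'
#' Probes are point samples at regular spacing: positions `0, s, 2s, ...`
#' strictly below `genome_length_bp`.
#'
#' @param genome_length_bp Chromosome length in bp.
#' @param probe_spacing_bp Spacing between probe positions in bp (> 0).
#' @return Integer vector of strictly increasing probe positions (0-based).
#' @examples
#' generate_probe_layout(350, 35)
#' @export
generate_probe_layout <- function(genome_length_bp, probe_spacing_bp = 35L) {
  if (probe_spacing_bp <= 0) tm_stop("probe_spacing_bp must be > 0")
  if (genome_length_bp < 1) tm_stop("genome_length_bp must be >= 1")
  as.integer(seq(0L, genome_length_bp - 1, by = probe_spacing_bp))
}

#' Generate a gene annotation and a heterochromatin partition
#'
#' Places `n_genes` non-overlapping genes on a single simulated chromosome,
#' allocates gene types by largest-remainder apportionment of
#' `gene_type_fractions`, and declares one pericentromeric heterochromatin
#' interval centred mid-chromosome covering `het_fraction` of the genome.
#' Transposon-related genes are preferentially assigned to gene slots whose
#' midpoint falls in heterochromatin (weight `te_het_enrichment`), emulating
#' pericentromeric TE clustering; each receives a `te_class` superfamily.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (data.frame: gene_id, chrom, start, end, strand,
#'   gene_type, te_class; 0-based half-open, sorted by start) and
#'   `heterochromatin` (data.frame: chrom, start, end).
#' @examples
#' ann <- generate_annotation(sim_config(seed = 1, genome_length_bp = 2e5,
#'                                       n_genes = 50))
#' table(ann$genes$gene_type)
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n < 1L) tm_stop("n_genes must be >= 1")
  G <- config$genome_length_bp
  withr::with_seed(config$seed, {
    len <- pmin(pmax(round(stats::rlnorm(n, log(1500), 0.6)), 200), 8000)
    min_gap <- 50
    slack <- G - sum(len) - (n + 1) * min_gap
    if (slack < 0) {
      tm_stop("infeasible gene placement: genome_length_bp = ", G,
              " cannot hold ", n, " genes totalling ", sum(len),
              " bp plus ", (n + 1) * min_gap, " bp of minimum intergenic gaps")
    }
    g <- stats::rexp(n + 1)
    gaps <- min_gap + slack * g / sum(g)
    start <- round(cumsum(gaps[seq_len(n)]) + cumsum(c(0, len[-n])))
    end <- start + len
    strand <- sample(c("+", "-"), n, replace = TRUE)

    het_w <- round(config$het_fraction * G)
    het_start <- round((G - het_w) / 2)
    het <- data.frame(chrom = config$chrom, start = het_start,
                      end = het_start + het_w)

    counts <- allocate_counts(config$gene_type_fractions, n)
    mid <- (start + end) / 2
    in_het <- mid >= het$start & mid < het$end
    gene_type <- character(n)
    idx <- seq_len(n)
    n_te <- counts["transposon"]
    if (!is.na(n_te) && n_te > 0L) {
      w <- ifelse(in_het, config$te_het_enrichment, 1)
      te_idx <- sample(idx, n_te, prob = w)
      gene_type[te_idx] <- "transposon"
      idx <- setdiff(idx, te_idx)
    }
    other <- rep(names(counts)[names(counts) != "transposon"],
                 counts[names(counts) != "transposon"])
    gene_type[sample(idx, length(idx))] <- other
    te_class <- rep(NA_character_, n)
    te <- gene_type == "transposon"
    te_class[te] <- sample(TE_CLASSES, sum(te), replace = TRUE,
                           prob = c(0.12, 0.10, 0.13, 0.65))
    genes <- data.frame(
      gene_id = sprintf("G%05d", seq_len(n)),
      chrom = config$chrom,
      start = as.integer(start), end = as.integer(end),
      strand = strand, gene_type = gene_type, te_class = te_class,
      stringsAsFactors = FALSE
    )
  })
  genes <- genes[order(genes$start), , drop = FALSE]
  genes$gene_id <- sprintf("G%05d", seq_len(n))  # ids follow coordinate order
  rownames(genes) <- NULL
  list(genes = check_genes(genes), heterochromatin = het)
}

#' Place non-overlapping enrichment regions to plant in IP channels
#'
#' Divides the genome into `n` equal slots and draws one region per slot with
#' a uniformly distributed length, keeping at least `min_gap` bp between
#' consecutive regions.  The default gap (2000 bp) exceeds the 1000-bp
#' merge gap of the region caller, so distinct planted regions cannot be
#' fused by gap-merging; enriched regions in this assay are sparse.
#'
#' @param n Number of regions.
#' @param genome_length_bp Genome length in bp.
#' @param length_range Numeric length 2: min/max region length in bp.
#' @param min_gap Minimum distance between consecutive regions in bp.
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @param mark Mark receiving the enrichment (one of [MARKS]).
#' @param effect_log2 Planted effect size in log2 units.
#' @return data.frame(chrom, start, end, mark, effect_log2), sorted.
#' @export
plant_regions <- function(n, genome_length_bp, length_range = c(400, 3000),
                          min_gap = 2000, seed = 1L, chrom = "chr1",
                          mark = "me2", effect_log2 = 2) {
  slot <- genome_length_bp / n
  if (slot < max(length_range) + min_gap) {
    tm_stop("cannot place ", n, " regions of up to ", max(length_range),
            " bp with ", min_gap, " bp gaps in ", genome_length_bp, " bp")
  }
  withr::with_seed(seed, {
    len <- round(stats::runif(n, length_range[1], length_range[2]))
    off <- stats::runif(n, min_gap / 2, slot - len - min_gap / 2)
    start <- round((seq_len(n) - 1) * slot + off)
  })
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len), mark = mark,
             effect_log2 = effect_log2, stringsAsFactors = FALSE)
}

#' Simulate a multi-mark ChIP tiling-array experiment
#'
#' For each requested mark, draws IP and input matrices (probes x replicates)
#' of linear-scale PM-MM values.  On the log2 scale, input is
#' `baseline_mean` + Gaussian noise; IP additionally carries the planted
#' `effect_log2` inside that mark's planted regions.  The total-H3 IP channel
#' carries a smooth sinusoidal nucleosome-occupancy field (amplitude
#' `occupancy_amplitude`, period 20 kb) independent of the marks.  Values are
#' exponentiated to the linear scale, and a fraction `neg_fraction` of
#' entries per matrix is forced non-positive to exercise the PM-MM flooring
#' rule of [log2_transform()].
#'
#' @param layout Integer probe positions from [generate_probe_layout()].
#' @param planted_regions data.frame(chrom, start, end, mark, effect_log2)
#'   or NULL; chromosomes must match `config$chrom`.
#' @param config A [sim_config()].
#' @param marks Character subset of [MARKS] to simulate.
#' @return Object of class `"chip_experiment"`: list with `chrom`,
#'   `positions`, and `marks` (per mark a list of `ip` and `input`
#'   matrices, probes x replicates, linear scale).
#' @export
generate_chip_experiment <- function(layout, planted_regions, config,
                                     marks = c("me2", "H3")) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(marks %in% MARKS)) {
    tm_stop("marks must be a subset of: ", paste(MARKS, collapse = ", "))
  }
  if (!is.null(planted_regions) && nrow(planted_regions) > 0L &&
      !all(planted_regions$chrom == config$chrom)) {
    tm_stop("planted region on unknown chromosome: ",
            paste(setdiff(unique(planted_regions$chrom), config$chrom),
                  collapse = ", "))
  }
  np <- length(layout)
  nr <- config$n_replicates
  rn <- paste0("rep", seq_len(nr))
  out <- vector("list", length(marks))
  names(out) <- marks
  withr::with_seed(config$seed + 1L, {
    phase <- stats::runif(1, 0, 2 * pi)
    occ <- config$occupancy_amplitude *
      sin(2 * pi * layout / 20000 + phase)
    for (m in marks) {
      eff <- numeric(np)
      if (!is.null(planted_regions)) {
        pr <- planted_regions[planted_regions$mark == m, , drop = FALSE]
        for (i in seq_len(nrow(pr))) {
          hit <- layout >= pr$start[i] & layout < pr$end[i]
          eff[hit] <- eff[hit] + pr$effect_log2[i]
        }
      }
      mu_ip <- config$baseline_mean + eff + if (m == "H3") occ else 0
      ip <- 2^(mu_ip + matrix(stats::rnorm(np * nr, 0, config$noise_sd),
                              np, nr))
      input <- 2^(config$baseline_mean +
                    matrix(stats::rnorm(np * nr, 0, config$noise_sd), np, nr))
      for (nmf in c("ip", "input")) {
        x <- get(nmf)
        k <- round(config$neg_fraction * length(x))
        if (k > 0L) {
          pick <- sample.int(length(x), k)
          x[pick] <- stats::runif(k, -2, 0)
          assign(nmf, x)
        }
      }
      dimnames(ip) <- dimnames(input) <- list(NULL, rn)
      out[[m]] <- list(ip = ip, input = input)
    }
  })
  structure(list(chrom = config$chrom, positions = as.integer(layout),
                 marks = out),
            class = "chip_experiment")
}

#' Simulate a genes x tissues expression matrix
#'
#' Each gene is assigned one expression archetype: `uniform` (identical
#' level in every tissue, entropy log2 n bits), `onehot` (expressed in a
#' single tissue, entropy 0), `sparse` (level spread by a Dirichlet(0.3)
#' draw, intermediate specificity), or `silent` (values at a ~0.01 noise
#' floor).  Per-gene overall levels are log-normal.
#'
#' @param genes Gene table (only `gene_id` is used) or a character vector of
#'   gene ids.
#' @param n_tissues Number of tissues (>= 2).
#' @param specificity_mix Named fractions over the four archetypes.
#' @param seed Integer seed.
#' @return Non-negative numeric matrix genes x tissues with gene ids as row
#'   names; the archetype of each gene is attached as attribute
#'   `"archetype"`.
#' @export
generate_expression <- function(genes, n_tissues = 8L,
                                specificity_mix = c(uniform = 0.35,
                                                    onehot = 0.15,
                                                    sparse = 0.40,
                                                    silent = 0.10),
                                seed = 1L) {
  ids <- if (is.character(genes)) genes else genes$gene_id
  n <- length(ids)
  if (n_tissues < 2) tm_stop("n_tissues must be >= 2")
  if (abs(sum(specificity_mix) - 1) > 1e-9) {
    tm_stop("specificity_mix must sum to 1")
  }
  withr::with_seed(seed, {
    arch <- sample(names(specificity_mix), n, replace = TRUE,
                   prob = specificity_mix)
    level <- 2^stats::rnorm(n, 6, 2)
    x <- matrix(0, n, n_tissues,
                dimnames = list(ids, paste0("tissue", seq_len(n_tissues))))
    for (i in seq_len(n)) {
      x[i, ] <- switch(arch[i],
        uniform = rep(level[i], n_tissues),
        onehot = {
          v <- numeric(n_tissues)
          v[sample.int(n_tissues, 1)] <- level[i]
          v
        },
        sparse = {
          g <- stats::rgamma(n_tissues, shape = 0.3) + 1e-12
          level[i] * n_tissues * g / sum(g)
        },
        silent = abs(stats::rnorm(n_tissues, 0, 0.01))
      )
    }
  })
  attr(x, "archetype") <- stats::setNames(arch, ids)
  x
}
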