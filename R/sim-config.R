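#' Simulation configuration for the synthetic tiling-array world
#'
#' Bundles every knob of the synthetic-data generators.  Defaults encode the
#' experimental design the pipeline targets: probes every 35 bp (the
#' resolution of the Affymetrix Arabidopsis Tiling 1.0R array), two
#' biological replicates per channel, and a gene-type mix matching the
#' genome-wide TAIR-style annotation counts (81.9% protein-coding, 11.8%
#' transposon-related, 2.6% pseudogene, the remainder small-RNA classes).
#'
#' @param seed Integer seed; every generator is a pure function of the
#'   configuration and this seed.  Must be below 2^30 (offsets are added
#'   internally per generator).
#' @param genome_length_bp Simulated chromosome length in bp.
#' @param probe_spacing_bp Distance between adjacent probe start positions,
#'   default 35 bp.
#' @param n_replicates Biological replicates per channel, default 2.
#' @param n_genes Number of genes to place.
#' @param gene_type_fractions Named numeric vector over [GENE_TYPES] summing
#'   to 1 (tolerance 1e-9); default is the genome-wide mix above.
#' @param planted_regions `data.frame(chrom, start, end, mark, effect_log2)`
#'   of enrichment blocks injected into IP channels (0-based half-open).
#' @param noise_sd Gaussian noise SD on the log2 scale, default 0.5
#'   (replicate-to-replicate spread typical of PM-MM tiling signal).
#' @param baseline_mean Baseline log2 signal, default 8 (linear ~256).
#' @param n_tissues Number of tissues for the expression matrix, default 8.
#' @param chrom Chromosome name used throughout, default `"chr1"`.
#' @param het_fraction Fraction of the genome declared pericentromeric
#'   heterochromatin (one interval centred mid-chromosome), default 0.2.
#' @param te_het_enrichment Preference weight for placing transposon-related
#'   genes inside heterochromatin, default 4 (4x over euchromatin).
#' @param neg_fraction Fraction of linear-scale PM-MM values forced <= 0 to
#'   exercise the flooring rule of [log2_transform()], default 0.01.
#' @param occupancy_amplitude Amplitude (log2 units) of the smooth
#'   nucleosome-occupancy field planted in the total-H3 IP channel,
#'   default 0.5.
#' @param specificity_mix Named fractions over the expression archetypes
#'   `uniform`, `onehot`, `sparse`, `silent`; must sum to 1.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, genome_length_bp = 1e5, n_genes = 20)
#' cfg$probe_spacing_bp
#' @export
sim_config <- function(seed,
                       genome_length_bp = 1e6,
                       probe_spacing_bp = 35L,
                       n_replicates = 2L,
                       n_genes = 200L,
                       gene_type_fractions = NULL,
                       planted_regions = NULL,
                       noise_sd = 0.5,
                       baseline_mean = 8,
                       n_tissues = 8L,
                       chrom = "chr1",
                       het_fraction = 0.2,
                       te_het_enrichment = 4,
                       neg_fraction = 0.01,
                       occupancy_amplitude = 0.5,
                       specificity_mix = c(uniform = 0.35, onehot = 0.15,
                                           sparse = 0.40, silent = 0.10)) {
  if (is.null(gene_type_fractions)) {
    counts <- c(protein_coding = 27025, transposon = 3900, pseudogene = 859,
                tRNA = 631, other_RNA = 326, miRNA = 174, snoRNA = 71,
                snRNA = 13, rRNA = 4)
    gene_type_fractions <- counts / sum(counts)
  }
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) >= 2^30) tm_stop("seed must be an integer below 2^30")
  if (probe_spacing_bp <= 0) tm_stop("probe_spacing_bp must be > 0")
  if (noise_sd <= 0) tm_stop("noise_sd must be > 0")
  if (n_replicates < 1) tm_stop("n_replicates must be >= 1")
  if (abs(sum(gene_type_fractions) - 1) > 1e-9) {
    tm_stop("gene_type_fractions must sum to 1 (tolerance 1e-9)")
  }
  if (!all(names(gene_type_fractions) %in% GENE_TYPES)) {
    tm_stop("gene_type_fractions names must be a subset of GENE_TYPES")
  }
  if (!is.null(planted_regions) && nrow(planted_regions) > 0L) {
    if (any(planted_regions$end <= planted_regions$start)) {
      tm_stop("planted regions must have end > start")
    }
    if (any(planted_regions$end > genome_length_bp |
            planted_regions$start < 0)) {
      tm_stop("planted regions must lie within [0, genome_length_bp)")
    }
    if (!all(planted_regions$mark %in% MARKS)) {
      tm_stop("planted region marks must be in: ", paste(MARKS, collapse = ", "))
    }
  }
  if (abs(sum(specificity_mix) - 1) > 1e-9) {
    tm_stop("specificity_mix must sum to 1")
  }
  if (n_tissues < 2) tm_stop("n_tissues must be >= 2")
  structure(list(
    seed = seed,
    genome_length_bp = as.numeric(genome_length_bp),
    probe_spacing_bp = as.integer(probe_spacing_bp),
    n_replicates = as.integer(n_replicates),
    n_genes = as.integer(n_genes),
    gene_type_fractions = gene_type_fractions,
    planted_regions = planted_regions,
    noise_sd = noise_sd,
    baseline_mean = baseline_mean,
    n_tissues = as.integer(n_tissues),
    chrom = chrom,
    het_fraction = het_fraction,
    te_het_enrichment = te_het_enrichment,
    neg_fraction = neg_fraction,
    occupancy_amplitude = occupancy_amplitude,
    specificity_mix = specificity_mix
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$genome_length_bp, "bp genome,",
      x$n_genes, "genes, probes every", x$probe_spacing_bp, "bp,",
      x$n_replicates, "replicates, seed", x$seed, "\n")
  invisible(x)
}
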