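# End-to-end pipeline: normalize -> call regions -> annotate -> profile ->
# cluster, driven by a JSON-serializable configuration, with a
# machine-readable report and an audit log of every parameter used.

#' Simulate a complete input data set on disk
#'
#' Generates an annotation (GFF3 + heterochromatin BED), a tiling signal
#' table with planted enriched regions, and an expression matrix, all under
#' one configuration, and writes them to `outdir`.
#'
#' @param config A [sim_config()]; if `config$planted_regions` is NULL,
#'   regions are planted with [plant_regions()] inside me2.
#' @param outdir Output directory (created if needed).
#' @param marks Marks to simulate.
#' @param n_regions Number of planted regions when none are supplied.
#' @return Named list of the file paths written, plus the `truth` planted
#'   regions, invisibly.
#' @export
simulate_dataset <- function(config, outdir, marks = c("me2", "me3", "H3"),
                             n_regions = 20L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(config)
  layout <- generate_probe_layout(config$genome_length_bp,
                                  config$probe_spacing_bp)
  planted <- config$planted_regions
  if (is.null(planted)) {
    planted <- plant_regions(n_regions, config$genome_length_bp,
                             seed = config$seed + 2L, chrom = config$chrom)
  }
  expt <- generate_chip_experiment(layout, planted, config, marks = marks)
  expr <- generate_expression(ann$genes, config$n_tissues,
                              config$specificity_mix,
                              seed = config$seed + 3L)
  paths <- list(
    gff3 = file.path(outdir, "genes.gff3"),
    het_bed = file.path(outdir, "heterochromatin.bed"),
    signal = file.path(outdir, "signal.tsv"),
    expression = file.path(outdir, "expression.tsv"),
    truth_bed = file.path(outdir, "planted_regions.bed")
  )
  write_gff3(ann$genes, paths$gff3)
  write_bed3(ann$heterochromatin, paths$het_bed)
  write_signal_table(expt, paths$signal)
  write_expression(expr, paths$expression)
  write_bed3(planted[, c("chrom", "start", "end")], paths$truth_bed)
  invisible(c(paths, list(truth = planted)))
}

#' Build a pipeline configuration
#'
#' @param signal Path to the TSV signal table.
#' @param gff3 Path to the GFF3 gene annotation.
#' @param outdir Output directory.
#' @param het_bed Optional heterochromatin BED path.
#' @param expression Optional expression TSV path.
#' @param h3_adjust Adjust enrichment tracks for total H3 before profiling
#'   and clustering (requires an H3 channel); default TRUE.
#' @param floor PM-MM flooring value for [log2_transform()].
#' @param hmm An [hmm_config()].
#' @param min_5prime,min_3prime Gene-spacing filter thresholds (bp).
#' @param window_bp Coverage window (bp), default 20000.
#' @param k_te,k_pc Cluster counts for transposon-related and protein-coding
#'   genes.
#' @param cluster_seed,n_restarts K-means seeding.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(signal, gff3, outdir,
                            het_bed = NULL, expression = NULL,
                            h3_adjust = TRUE, floor = 1,
                            hmm = hmm_config(),
                            min_5prime = 350, min_3prime = 150,
                            window_bp = 20000L,
                            k_te = 4L, k_pc = 5L,
                            cluster_seed = 1L, n_restarts = 10L) {
  cfg <- list(signal = signal, gff3 = gff3, outdir = outdir,
              het_bed = het_bed, expression = expression,
              h3_adjust = h3_adjust, floor = floor, hmm = hmm,
              min_5prime = min_5prime, min_3prime = min_3prime,
              window_bp = as.integer(window_bp),
              k_te = as.integer(k_te), k_pc = as.integer(k_pc),
              cluster_seed = as.integer(cluster_seed),
              n_restarts = as.integer(n_restarts))
  for (f in c("signal", "gff3")) {
    if (!file.exists(cfg[[f]])) tm_stop("missing input file (", f, "): ",
                                        cfg[[f]])
  }
  for (f in c("het_bed", "expression")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      tm_stop("missing input file (", f, "): ", cfg[[f]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with the fields of [pipeline_config()]; `hmm` may
#'   be a sub-object with [hmm_config()] fields.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$hmm)) raw$hmm <- do.call(hmm_config, as.list(raw$hmm))
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Chains normalization, region calling, annotation statistics, positional
#' profiling and clustering over every chromosome of the signal table, and
#' writes BED/bedGraph/TSV outputs, a JSON report and an audit log to the
#' configured output directory.
#'
#' @param config A `"pipeline_config"` (or path to a JSON one).
#' @return The report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      tm_stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  tracks <- stage("read", read_signal_table(config$signal))
  genes <- stage("read", read_gff3(config$gff3))
  het <- if (!is.null(config$het_bed)) stage("read", read_bed(config$het_bed))
  expr <- if (!is.null(config$expression)) {
    stage("read", read_expression(config$expression))
  }

  chrom_lengths <- vapply(tracks, function(tr) {
    md <- if (length(tr$positions) > 1L) stats::median(diff(tr$positions))
      else 1
    max(tr$positions) + md
  }, numeric(1))
  marks <- setdiff(names(tracks[[1]]$marks), "H3")
  has_h3 <- "H3" %in% names(tracks[[1]]$marks)
  if (config$h3_adjust && !has_h3) {
    tm_stop("h3_adjust = TRUE but the signal table has no H3 channel")
  }

  norm_tracks <- list()    # [[mark]][[chrom]] enrichment_track for profiles
  regions <- list()        # [[mark]] region table across chroms
  for (m in marks) norm_tracks[[m]] <- list()
  stage("normalize/callpeaks", for (chr in names(tracks)) {
    tr <- tracks[[chr]]
    h3_lr <- if (has_h3) {
      normalize_mark(
        probe_track(chr, tr$positions, tr$marks$H3$ip),
        probe_track(chr, tr$positions, tr$marks$H3$input),
        floor = config$floor)
    }
    for (m in marks) {
      ip_raw <- probe_track(chr, tr$positions, tr$marks[[m]]$ip)
      in_raw <- probe_track(chr, tr$positions, tr$marks[[m]]$input)
      lr <- normalize_mark(ip_raw, in_raw, floor = config$floor)
      norm_tracks[[m]][[chr]] <- if (config$h3_adjust) {
        h3_adjust(lr, h3_lr)
      } else lr
      ip <- quantile_normalize(log2_transform(ip_raw, config$floor))
      input <- quantile_normalize(log2_transform(in_raw, config$floor))
      tt <- probe_t_statistics(ip, input,
                               config$hmm$variance_shrinkage_weight)
      fit <- fit_two_state_hmm(tt, config$hmm)
      reg <- call_regions(fit$posterior, tr$positions, config$hmm,
                          chrom = chr)
      regions[[m]] <- rbind(regions[[m]], reg)
    }
  })

  report <- list(parameters = list(
    max_gap_bp = config$hmm$max_gap_bp, min_run_bp = config$hmm$min_run_bp,
    posterior_cutoff = config$hmm$posterior_cutoff,
    min_5prime = config$min_5prime, min_3prime = config$min_3prime,
    window_bp = config$window_bp, h3_adjust = config$h3_adjust,
    floor = config$floor, k_te = config$k_te, k_pc = config$k_pc,
    cluster_seed = config$cluster_seed))

  flags <- list()
  stage("annotate", for (m in marks) {
    write_bed(regions[[m]], file.path(config$outdir,
                                      sprintf("peaks_%s.bed", m)))
    cov <- coverage_track(regions[[m]], chrom_lengths, config$window_bp)
    utils::write.table(cov,
                       file.path(config$outdir,
                                 sprintf("coverage_%s.tsv", m)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    flags[[m]] <- link_regions_to_genes(regions[[m]], genes)
    tab <- gene_type_table(flags[[m]], genes)
    utils::write.table(tab,
                       file.path(config$outdir,
                                 sprintf("gene_type_table_%s.tsv", m)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$regions[[m]] <- region_size_summary(regions[[m]])
    report$gene_type_table[[m]] <- tab
    report$n_enriched_genes[[m]] <- sum(flags[[m]])
    if (!is.null(het)) {
      strat <- stratified_enrichment(flags[[m]], genes, het)
      report$stratified[[m]] <- list(
        heterochromatin = strat$heterochromatin,
        euchromatin = strat$euchromatin)
    }
    report$long_regions[[m]] <- long_region_composition(regions[[m]], genes)
  })
  if (all(c("me2", "me3") %in% marks)) {
    report$me2_me3_overlap <-
      set_overlap_test(flags[["me2"]], flags[["me3"]])
  }

  spaced <- stage("profile", select_spaced_genes(genes, config$min_5prime,
                                                 config$min_3prime))
  report$n_spaced_genes <- nrow(spaced)
  profs <- list()
  stage("profile", for (m in marks) {
    pm <- do.call(rbind, lapply(names(norm_tracks[[m]]), function(chr) {
      g <- spaced[spaced$chrom == chr, , drop = FALSE]
      if (nrow(g) == 0L) return(NULL)
      suppressWarnings(profile_matrix(norm_tracks[[m]][[chr]], g))
    }))
    pm <- pm[match(spaced$gene_id, rownames(pm)), , drop = FALSE]
    pm <- pm[!is.na(rownames(pm)), , drop = FALSE]
    profs[[m]] <- pm
    utils::write.table(
      data.frame(gene_id = rownames(pm), pm, check.names = FALSE),
      file.path(config$outdir, sprintf("profiles_%s.tsv", m)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("cluster", for (cls in c("transposon", "protein_coding")) {
    k <- if (cls == "transposon") config$k_te else config$k_pc
    ids <- spaced$gene_id[spaced$gene_type == cls]
    sets <- lapply(profs, function(p) p[rownames(p) %in% ids, ,
                                        drop = FALSE])
    n_ok <- nrow(sets[[1]])
    if (n_ok >= max(k, 2L)) {
      cl <- concat_and_cluster(sets, k = k, seed = config$cluster_seed,
                               n_restarts = config$n_restarts)
      utils::write.table(
        data.frame(gene_id = names(cl$assignments),
                   cluster = cl$assignments),
        file.path(config$outdir, sprintf("clusters_%s.tsv", cls)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      report$clusters[[cls]] <- list(
        k = k, sizes = as.integer(table(cl$assignments)),
        within_cluster_ss = cl$within_cluster_ss)
      if (!is.null(expr)) {
        common <- intersect(names(cl$assignments), rownames(expr))
        if (length(common) >= k) {
          report$cluster_expression[[cls]] <- expression_group_summary(
            expr[common, , drop = FALSE], cl$assignments[common])
        }
      }
    }
  })

  if (!is.null(expr) && "me2" %in% names(profs)) {
    stage("decile", {
      pc <- profs$me2[rownames(profs$me2) %in%
                        spaced$gene_id[spaced$gene_type == "protein_coding"],
                      , drop = FALSE]
      common <- intersect(rownames(pc), rownames(expr))
      if (length(common) >= 10L) {
        level <- rowMeans(expr[common, , drop = FALSE])
        dec <- decile_profiles(pc[common, , drop = FALSE], level)
        report$decile_profiles_me2 <- dec$profiles
      }
    })
  }

  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       na = "null")
  log_lines <- c(
    paste("tilemark", as.character(utils::packageVersion("tilemark"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    vapply(names(report$parameters), function(p) {
      paste0(p, " = ", report$parameters[[p]])
    }, character(1)))
  writeLines(log_lines, file.path(config$outdir, "pipeline.log"))
  invisible(report)
}
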