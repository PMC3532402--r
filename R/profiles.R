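# Fixed 15-bin genic positional profiles.  The window schema reconciles the
# five anatomical window classes (promoter / TSS / proportional gene body /
# 3' end / 3' flank) with a fixed 15-column layout:
#   P1-P3  three 100-bp proximal-promoter windows (-350..-50 relative to TSS)
#   TSS    -49 bp through 5% of the transcribed region
#   B1-B9  nine 10% intervals of the transcribed region (5% to 95%)
#   E      95%-100% of the transcribed region plus 50 bp beyond the 3' end
#   F      the next 100 bp of 3' flank
# All windows are half-open on probe point coordinates and follow
# transcription orientation (mirrored for minus-strand genes).

#' Labels of the 15 positional-profile bins
#' @format Character vector of length 15.
#' @export
PROFILE_BINS <- c("P1", "P2", "P3", "TSS", paste0("B", 1:9), "E", "F")

# window boundaries in transcription-oriented coordinates (d = signed bp
# from the TSS); returns a 15 x 2 matrix of [lo, hi)
profile_windows <- function(gene_length) {
  L <- gene_length
  body <- 0.05 * L + 0.1 * L * (0:9)
  lo <- c(-350, -250, -150, -49, body[1:9], 0.95 * L, L + 50)
  hi <- c(-250, -150, -50, body[1], body[2:10], L + 50, L + 150)
  cbind(lo, hi)
}

#' Select genes sufficiently spaced from their neighbors
#'
#' Keeps a gene iff the nearest neighboring gene boundary is at least
#' `min_5prime` bp away on its 5' side and `min_3prime` bp away on its 3'
#' side, measured boundary-to-boundary in transcription orientation.
#' Chromosome-terminal genes pass automatically on their unbounded side;
#' overlapping neighbors produce non-positive gaps and fail.
#'
#' @param genes Gene table.
#' @param min_5prime Minimum 5'-side intergenic gap (bp), default 350.
#' @param min_3prime Minimum 3'-side intergenic gap (bp), default 150.
#' @return The subset of `genes` passing both rules (row order preserved).
#' @export
select_spaced_genes <- function(genes, min_5prime = 350, min_3prime = 150) {
  check_genes(genes)
  keep <- rep(TRUE, nrow(genes))
  for (chr in unique(genes$chrom)) {
    idx <- which(genes$chrom == chr)
    g <- genes[idx, , drop = FALSE]
    left_gap <- vapply(seq_len(nrow(g)), function(i) {
      j <- which(g$start < g$start[i])
      j <- j[j != i]
      if (length(j) == 0L) Inf else g$start[i] - max(g$end[j])
    }, numeric(1))
    right_gap <- vapply(seq_len(nrow(g)), function(i) {
      j <- which(g$start > g$start[i])
      if (length(j) == 0L) Inf else min(g$start[j]) - g$end[i]
    }, numeric(1))
    plus <- g$strand == "+"
    gap5 <- ifelse(plus, left_gap, right_gap)
    gap3 <- ifelse(plus, right_gap, left_gap)
    keep[idx] <- gap5 >= min_5prime & gap3 >= min_3prime
  }
  genes[keep, , drop = FALSE]
}

#' Positional profile of one gene on one enrichment track
#'
#' Each bin is the mean track value over probes whose point coordinate falls
#' in the bin's half-open genomic window; bins containing no probe are
#' `NA`.  For minus-strand genes all windows are mirrored about the gene so
#' bin 1 is always promoter-proximal.
#'
#' @param track An `"enrichment_track"`.
#' @param gene One-row gene table (transcribed length >= `min_length`).
#' @param min_length Minimum transcribed length (bp), default 20 (so the 10%
#'   body intervals are non-degenerate); shorter genes return `NULL` with a
#'   warning.
#' @return Named numeric vector of length 15 ([PROFILE_BINS]), or `NULL`.
#' @export
positional_profile <- function(track, gene, min_length = 20) {
  stopifnot(inherits(track, "enrichment_track"))
  L <- gene$end - gene$start
  if (L < min_length) {
    warning("gene ", gene$gene_id, " shorter than ", min_length,
            " bp: skipped", call. = FALSE)
    return(NULL)
  }
  if (!identical(gene$chrom, track$chrom)) {
    return(stats::setNames(rep(NA_real_, 15L), PROFILE_BINS))
  }
  # transcription-oriented signed distance of each probe from the TSS
  d <- if (gene$strand == "+") {
    track$positions - gene$start
  } else {
    (gene$end - 1) - track$positions
  }
  win <- profile_windows(L)
  prof <- vapply(seq_len(15L), function(b) {
    v <- track$value[d >= win[b, 1] & d < win[b, 2]]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  stats::setNames(prof, PROFILE_BINS)
}

#' Positional profiles for a set of genes
#'
#' @param track An `"enrichment_track"`.
#' @param genes Gene table; genes shorter than `min_length` are skipped with
#'   one collected warning.
#' @param min_length Passed to [positional_profile()].
#' @return Numeric matrix genes x 15 with gene ids as row names.
#' @export
profile_matrix <- function(track, genes, min_length = 20) {
  check_genes(genes)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    suppressWarnings(positional_profile(track, genes[i, , drop = FALSE],
                                        min_length))
  })
  skipped <- vapply(rows, is.null, logical(1))
  if (any(skipped)) {
    warning(sum(skipped), " gene(s) shorter than ", min_length,
            " bp skipped", call. = FALSE)
  }
  m <- do.call(rbind, rows[!skipped])
  rownames(m) <- genes$gene_id[!skipped]
  colnames(m) <- PROFILE_BINS
  m
}

#' Mean profile per group
#'
#' @param profiles Matrix genes x 15 (rows may contain `NA` bins).
#' @param group_assignment Group label per row of `profiles`.
#' @return Matrix groups x 15 of per-bin means over non-missing values; a
#'   bin missing in every member is `NA`.  Empty groups (levels of a factor
#'   with no members) raise an error naming the group.
#' @export
group_mean_profile <- function(profiles, group_assignment) {
  if (nrow(profiles) != length(group_assignment)) {
    tm_stop("profiles and group_assignment differ in length")
  }
  ga <- as.factor(group_assignment)
  n_by_group <- table(ga)
  if (any(n_by_group == 0L)) {
    tm_stop("empty group: ", paste(names(n_by_group)[n_by_group == 0L],
                                   collapse = ", "))
  }
  out <- t(vapply(levels(ga), function(g) {
    m <- colMeans(profiles[ga == g, , drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  }, numeric(ncol(profiles))))
  colnames(out) <- colnames(profiles)
  out
}

#' Mean profiles by expression decile
#'
#' Genes are ranked by expression (ties broken by stable gene-id order) and
#' split into 10 bins of equal size, any remainder going to the lower
#' deciles; decile 1 holds the least-expressed genes.
#'
#' @param profiles Matrix genes x 15 with gene ids as row names.
#' @param expression_levels Named (or positionally matched) expression value
#'   per profiled gene.
#' @return List: `profiles` (10 x 15 matrix of decile means, rows
#'   `decile01`..`decile10`), `decile` (assignment per gene).
#' @export
decile_profiles <- function(profiles, expression_levels) {
  n <- nrow(profiles)
  if (n < 10L) tm_stop("decile profiles need >= 10 genes")
  if (length(expression_levels) != n) {
    tm_stop("expression_levels and profiles differ in length")
  }
  if (!is.null(names(expression_levels)) && !is.null(rownames(profiles))) {
    if (!setequal(names(expression_levels), rownames(profiles))) {
      tm_stop("expression_levels names do not match profile rows")
    }
    expression_levels <- expression_levels[rownames(profiles)]
  }
  ord <- order(expression_levels, rownames(profiles))
  base <- n %/% 10L
  rem <- n %% 10L
  sizes <- base + as.integer(seq_len(10L) <= rem)
  dec <- integer(n)
  dec[ord] <- rep(seq_len(10L), times = sizes)
  means <- group_mean_profile(profiles, factor(dec, levels = 1:10))
  rownames(means) <- sprintf("decile%02d", 1:10)
  list(profiles = means,
       decile = stats::setNames(dec, rownames(profiles)))
}

#' Bin-wise difference of two profiles (e.g. me2 relative to me3)
#'
#' @param profile_a,profile_b Vectors or matrices with an identical 15-bin
#'   schema (both on the log2 relative-to-H3 scale); missing values
#'   propagate.
#' @return `profile_a - profile_b`.
#' @export
relative_profile <- function(profile_a, profile_b) {
  if (!identical(dim(profile_a), dim(profile_b)) ||
      !identical(length(profile_a), length(profile_b))) {
    tm_stop("profile schemas differ in shape")
  }
  na <- if (is.matrix(profile_a)) colnames(profile_a) else names(profile_a)
  nb <- if (is.matrix(profile_b)) colnames(profile_b) else names(profile_b)
  if (!is.null(na) && !is.null(nb) && !identical(na, nb)) {
    tm_stop("profile schemas differ in bin labels")
  }
  profile_a - profile_b
}
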