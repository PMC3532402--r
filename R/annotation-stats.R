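# Region-to-gene linkage and gene-type representation statistics: Fisher's
# exact tests per gene type, mark-set overlap chi-square, stratification by
# the euchromatin/heterochromatin partition, and transposon-superfamily
# composition of long enriched regions.

#' Two-sided Fisher's exact p for a 2x2 table
#'
#' Conditional on the margins, sums the hypergeometric probabilities of all
#' tables whose probability does not exceed that of the observed table (with
#' the customary `1 + 1e-7` relative tolerance for equal-probability
#' tables).  Table layout: `[a b; c d]`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_p(3, 1, 1, 3)
#' @export
fisher_exact_p <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) tm_stop("cell counts must be non-negative")
  m <- a + b        # row 1 total
  n <- c + d        # row 2 total
  k <- a + c        # column 1 total
  if (m + n == 0L) return(1)
  support <- max(0L, k - n):min(m, k)
  dens <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

#' Flag genes overlapped by enriched regions
#'
#' A gene is enriched if any segment of its annotated transcribed region
#' (`[start, end)`) overlaps an enriched region by at least one base;
#' promoter-only overlap does not count.
#'
#' @param regions Region table (chrom, start, end; 0-based half-open).
#' @param genes Gene table (see [generate_annotation()]).
#' @return Logical vector, one flag per row of `genes`.
#' @export
link_regions_to_genes <- function(regions, genes) {
  check_regions(regions)
  check_genes(genes)
  if (nrow(regions) == 0L) return(rep(FALSE, nrow(genes)))
  hits <- GenomicRanges::findOverlaps(
    as_granges0(genes), as_granges0(regions),
    minoverlap = 1L, ignore.strand = TRUE)
  flags <- rep(FALSE, nrow(genes))
  flags[unique(S4Vectors::queryHits(hits))] <- TRUE
  flags
}

#' Gene-type representation table with Fisher's exact tests
#'
#' For every gene type, tabulates counts and percentages within the entire
#' gene set and within the enriched set, and tests over/underrepresentation
#' of the type among enriched genes with a two-sided Fisher's exact test on
#' the 2x2 (type vs other) x (enriched vs not).  No correction is applied
#' across types (matching the customary presentation of raw Fisher bounds);
#' a Bonferroni column is emitted for transparency.
#'
#' @param flags Logical enriched flag per gene.
#' @param genes Gene table.
#' @return data.frame with one row per [GENE_TYPES]: `gene_type`,
#'   `count_entire`, `pct_entire`, `count_enriched`, `pct_enriched`,
#'   `fisher_p`, `fisher_p_bonferroni`, `direction` ("over"/"under"/"none").
#' @export
gene_type_table <- function(flags, genes) {
  check_genes(genes)
  if (length(flags) != nrow(genes)) {
    tm_stop("flags and genes differ in length")
  }
  total <- nrow(genes)
  n_enr <- sum(flags)
  types <- factor(genes$gene_type, levels = GENE_TYPES)
  count_entire <- as.integer(table(types))
  count_enriched <- as.integer(table(types[flags]))
  pct_entire <- 100 * count_entire / total
  pct_enriched <- if (n_enr > 0L) 100 * count_enriched / n_enr else
    rep(0, length(GENE_TYPES))
  fisher_p <- vapply(seq_along(GENE_TYPES), function(i) {
    if (n_enr == 0L) return(1)
    a <- count_enriched[i]
    b <- n_enr - a
    c <- count_entire[i] - a
    d <- (total - n_enr) - c
    fisher_exact_p(a, b, c, d)
  }, numeric(1))
  direction <- ifelse(
    n_enr == 0L | pct_enriched == pct_entire, "none",
    ifelse(pct_enriched > pct_entire, "over", "under"))
  data.frame(gene_type = GENE_TYPES,
             count_entire = count_entire, pct_entire = pct_entire,
             count_enriched = count_enriched, pct_enriched = pct_enriched,
             fisher_p = fisher_p,
             fisher_p_bonferroni = pmin(1, fisher_p * length(GENE_TYPES)),
             direction = direction,
             stringsAsFactors = FALSE)
}

#' Chi-square test of overlap between two enriched gene sets
#'
#' Under independence the expected overlap is `N * p_A * p_B`; the test is a
#' chi-square test of independence on the 2x2 cross-classification, without
#' continuity correction by default.
#'
#' @param flags_a,flags_b Logical flags over the same gene universe.
#' @param correct Apply Yates continuity correction; default `FALSE`.
#' @return List: `observed_overlap`, `expected_overlap`, `chi_square_p`.
#' @export
set_overlap_test <- function(flags_a, flags_b, correct = FALSE) {
  if (length(flags_a) == 0L) tm_stop("empty gene universe")
  if (length(flags_a) != length(flags_b)) {
    tm_stop("flag vectors differ in length")
  }
  n <- length(flags_a)
  obs <- sum(flags_a & flags_b)
  expd <- n * mean(flags_a) * mean(flags_b)
  tab <- table(factor(flags_a, c(FALSE, TRUE)),
               factor(flags_b, c(FALSE, TRUE)))
  p <- if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    1  # a degenerate margin carries no information about association
  } else {
    suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
  }
  list(observed_overlap = obs, expected_overlap = expd, chi_square_p = p)
}

#' Gene-type tables stratified by the heterochromatin partition
#'
#' A gene belongs to heterochromatin iff its midpoint
#' (`floor((start + end) / 2)`) lies in a heterochromatin interval
#' (half-open, so a midpoint exactly on an interval end is euchromatic).
#'
#' @param flags Logical enriched flag per gene.
#' @param genes Gene table.
#' @param het_intervals data.frame(chrom, start, end) of non-overlapping
#'   heterochromatin intervals (0-based half-open).
#' @return List with elements `heterochromatin` and `euchromatin`, each a
#'   [gene_type_table()] data.frame, plus `in_het` (the logical assignment).
#' @export
stratified_enrichment <- function(flags, genes, het_intervals) {
  check_genes(genes)
  mid <- floor((genes$start + genes$end) / 2)
  in_het <- rep(FALSE, nrow(genes))
  for (i in seq_len(nrow(het_intervals))) {
    in_het <- in_het | (genes$chrom == het_intervals$chrom[i] &
                          mid >= het_intervals$start[i] &
                          mid < het_intervals$end[i])
  }
  list(
    heterochromatin = gene_type_table(flags[in_het],
                                      genes[in_het, , drop = FALSE]),
    euchromatin = gene_type_table(flags[!in_het],
                                  genes[!in_het, , drop = FALSE]),
    in_het = in_het
  )
}

#' Transposon-superfamily composition of long enriched regions
#'
#' Restricts to regions at least `min_len` bp long, tabulates the `te_class`
#' of transposon-related genes they overlap, and compares the share of the
#' focal retroelement superfamilies (LINE/L1, LTR/Copia, LTR/Gypsy) against
#' the composition of all transposon genes whose annotated length falls in
#' `size_band`, with a two-sided Fisher's exact test on (focal vs other) x
#' (in long regions vs not).
#'
#' @param regions Region table.
#' @param genes Gene table; transposon genes must carry `te_class`.
#' @param min_len Minimum region length (bp), default 1000.
#' @param size_band Length band (bp, inclusive) defining the background TE
#'   set, default `c(1000, 4000)`.
#' @param focal_classes Superfamilies counted as focal.
#' @return List: `composition` (named counts over [TE_CLASSES] for TEs in
#'   long regions), `pct_focal_long`, `background_composition`,
#'   `pct_focal_background`, `fisher_p` (`NA` when no long-region TEs).
#' @export
long_region_composition <- function(regions, genes, min_len = 1000,
                                    size_band = c(1000, 4000),
                                    focal_classes = c("LINE/L1", "LTR/Copia",
                                                      "LTR/Gypsy")) {
  check_regions(regions)
  check_genes(genes)
  long <- regions[regions$end - regions$start >= min_len, , drop = FALSE]
  te <- genes[genes$gene_type == "transposon", , drop = FALSE]
  if (nrow(te) > 0L && any(is.na(te$te_class))) {
    tm_stop("transposon genes must carry te_class")
  }
  empty <- stats::setNames(integer(length(TE_CLASSES)), TE_CLASSES)
  if (nrow(long) == 0L || nrow(te) == 0L) {
    return(list(composition = empty, pct_focal_long = NA_real_,
                background_composition = empty,
                pct_focal_background = NA_real_, fisher_p = NA_real_))
  }
  in_long <- link_regions_to_genes(long, te)
  comp <- table(factor(te$te_class[in_long], TE_CLASSES))
  te_len <- te$end - te$start
  in_band <- te_len >= size_band[1] & te_len <= size_band[2]
  bg <- in_band & !in_long
  bg_comp <- table(factor(te$te_class[bg], TE_CLASSES))
  focal <- te$te_class %in% focal_classes
  a <- sum(focal & in_long)
  b <- sum(!focal & in_long)
  c <- sum(focal & bg)
  d <- sum(!focal & bg)
  p <- if (sum(in_long) == 0L) NA_real_ else fisher_exact_p(a, b, c, d)
  list(
    composition = stats::setNames(as.integer(comp), TE_CLASSES),
    pct_focal_long = if (sum(in_long) > 0L) 100 * a / sum(in_long)
      else NA_real_,
    background_composition = stats::setNames(as.integer(bg_comp), TE_CLASSES),
    pct_focal_background = if (sum(bg) > 0L) 100 * c / sum(bg) else NA_real_,
    fisher_p = p
  )
}
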