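# Multi-mark chromatin-state clustering and expression summaries: K-means on
# concatenated positional profiles, Shannon-entropy tissue specificity, and
# per-group quartile summaries.

#' K-means clustering of concatenated multi-mark profiles
#'
#' Concatenates one 15-bin profile matrix per mark into a single
#' `genes x (15 * n_marks)` matrix, drops genes with more than 50% missing
#' bins, imputes remaining missing bins with 0 (the neutral value on the
#' log2 relative-to-H3 scale), and runs K-means with Euclidean distance,
#' keeping the best of `n_restarts` seeded restarts.  Rows are first sorted
#' by gene id so the result is invariant to input order.  Profiles are not
#' z-scored by default (the signed log2 scale is shared across histone
#' marks); set `scale_marks = TRUE` to min-max scale each mark's block,
#' e.g. when mixing in a fraction-scale DNA-methylation track.
#'
#' @param profile_sets Named list of genes x 15 matrices, identical row
#'   names across marks.
#' @param k Number of clusters (>= 1; documented defaults are 4 for
#'   transposon-related genes and 5 for protein-coding genes).
#' @param seed Integer seed for the restarts.
#' @param n_restarts Number of random restarts, default 10.
#' @param scale_marks Min-max scale each mark block before concatenation.
#' @return Object of class `"cluster_result"`: list with `gene_ids`,
#'   `assignments` (labels in `1..k`, named by gene), `centroids`
#'   (k x 15*n_marks), `within_cluster_ss`, `k`, `seed`, `dropped`
#'   (gene ids excluded for missingness).
#' @export
concat_and_cluster <- function(profile_sets, k, seed = 1L, n_restarts = 10L,
                               scale_marks = FALSE) {
  if (!is.list(profile_sets) || length(profile_sets) == 0L) {
    tm_stop("profile_sets must be a non-empty list of matrices")
  }
  ids <- rownames(profile_sets[[1]])
  for (m in profile_sets) {
    if (!identical(rownames(m), ids)) {
      tm_stop("profile matrices must share the same gene order")
    }
  }
  ord <- order(ids)
  mats <- lapply(profile_sets, function(m) m[ord, , drop = FALSE])
  if (scale_marks) {
    mats <- lapply(mats, function(m) {
      rng <- range(m, na.rm = TRUE)
      if (diff(rng) == 0) m * 0 else (m - rng[1]) / diff(rng)
    })
  }
  x <- do.call(cbind, mats)
  colnames(x) <- unlist(lapply(names(profile_sets),
                               function(nm) paste(nm, PROFILE_BINS,
                                                  sep = ".")))
  miss <- rowMeans(is.na(x))
  keep <- miss <= 0.5
  x <- x[keep, , drop = FALSE]
  x[is.na(x)] <- 0
  if (k > nrow(x)) tm_stop("k = ", k, " exceeds ", nrow(x), " usable genes")
  if (k < 1L) tm_stop("k must be >= 1")
  km <- withr::with_seed(seed,
                         stats::kmeans(x, centers = k, nstart = n_restarts,
                                       iter.max = 100L))
  structure(list(
    gene_ids = rownames(x),
    assignments = stats::setNames(km$cluster, rownames(x)),
    centroids = km$centers,
    within_cluster_ss = km$tot.withinss,
    k = k, seed = seed,
    dropped = ids[ord][!keep]
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: k =", x$k, "on", length(x$gene_ids), "genes;",
      "cluster sizes:", paste(table(x$assignments), collapse = ", "), "\n")
  invisible(x)
}

#' Shannon entropy of a gene's tissue-expression distribution
#'
#' `H = -sum(p * log2(p))` over tissues with `p = x / sum(x)`; 0 bits means
#' fully tissue-specific expression and `log2(n_tissues)` bits means uniform
#' expression.  An all-zero vector has no defined distribution and returns
#' `NA`.
#'
#' @param x Non-negative expression vector across tissues.
#' @return Entropy in bits, or `NA_real_` for all-zero input.
#' @examples
#' shannon_entropy(rep(1, 8))       # 3 bits
#' shannon_entropy(c(1, 0, 0, 0))   # 0 bits
#' @export
shannon_entropy <- function(x) {
  if (any(x < 0)) tm_stop("expression values must be non-negative")
  s <- sum(x)
  if (s == 0) return(NA_real_)
  p <- x / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-group quartiles of expression level and entropy
#'
#' Expression level is the mean across tissues; tissue specificity is
#' [shannon_entropy()].  Quartiles use linear interpolation between order
#' statistics (`stats::quantile` type 7).
#'
#' @param expression Matrix genes x tissues with gene ids as row names.
#' @param group_assignment Group label per gene (same order as rows).
#' @return data.frame with one row per group: `group`, `n`, `level_q25`,
#'   `level_q50`, `level_q75`, `entropy_q25`, `entropy_q50`, `entropy_q75`.
#' @export
expression_group_summary <- function(expression, group_assignment) {
  if (nrow(expression) != length(group_assignment)) {
    tm_stop("expression and group_assignment differ in length")
  }
  ga <- as.factor(group_assignment)
  if (any(table(ga) == 0L)) {
    tm_stop("empty group: ",
            paste(names(table(ga))[table(ga) == 0L], collapse = ", "))
  }
  level <- rowMeans(expression)
  ent <- apply(expression, 1, shannon_entropy)
  q <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE,
                                   names = FALSE, type = 7)
  rows <- lapply(levels(ga), function(g) {
    sel <- ga == g
    ql <- q(level[sel])
    qe <- q(ent[sel])
    data.frame(group = g, n = sum(sel),
               level_q25 = ql[1], level_q50 = ql[2], level_q75 = ql[3],
               entropy_q25 = qe[1], entropy_q50 = qe[2], entropy_q75 = qe[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
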