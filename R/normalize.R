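# Probe-level normalization: log2 transform with PM-MM flooring, quantile
# normalization across replicates, channel scaling to a common mean, IP/input
# log ratio and adjustment for total H3.

#' Construct a probe track (per-replicate probe signals on one chromosome)
#'
#' @param chrom Chromosome name.
#' @param positions Strictly increasing integer probe positions (0-based).
#' @param values Numeric matrix probes x replicates.
#' @return Object of class `"probe_track"`.
#' @export
probe_track <- function(chrom, positions, values) {
  values <- as.matrix(values)
  if (length(positions) != nrow(values)) {
    tm_stop("positions and values rows differ in length")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    tm_stop("probe positions must be strictly increasing")
  }
  structure(list(chrom = chrom, positions = as.integer(positions),
                 values = values),
            class = "probe_track")
}

#' Construct an enrichment track (one value per probe)
#'
#' @param chrom Chromosome name.
#' @param positions Strictly increasing integer probe positions (0-based).
#' @param value Numeric vector, one value per probe; must be finite.
#' @return Object of class `"enrichment_track"`.
#' @export
enrichment_track <- function(chrom, positions, value) {
  if (length(positions) != length(value)) {
    tm_stop("positions and value differ in length")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    tm_stop("probe positions must be strictly increasing")
  }
  if (!all(is.finite(value))) tm_stop("enrichment track values must be finite")
  structure(list(chrom = chrom, positions = as.integer(positions),
                 value = as.numeric(value)),
            class = "enrichment_track")
}

#' @export
print.probe_track <- function(x, ...) {
  cat("probe_track:", x$chrom, "-", length(x$positions), "probes x",
      ncol(x$values), "replicates\n")
  invisible(x)
}

#' @export
print.enrichment_track <- function(x, ...) {
  cat("enrichment_track:", x$chrom, "-", length(x$positions), "probes,",
      "mean", signif(mean(x$value), 4), "\n")
  invisible(x)
}

same_probes <- function(a, b, what = "tracks") {
  if (!identical(a$chrom, b$chrom) ||
      !identical(a$positions, b$positions)) {
    tm_stop(what, " are defined on different probe sets")
  }
  invisible(TRUE)
}

#' Log2-transform linear PM-MM signals with flooring
#'
#' PM-MM differences can be non-positive on real arrays; values below
#' `floor` are raised to `floor` before taking log2 (so the default floor of
#' 1 maps them to 0).
#'
#' @param x Numeric vector/matrix of linear-scale values, or a
#'   `"probe_track"` holding them.
#' @param floor Positive flooring value, default 1.
#' @return Same shape/class as `x`, values `log2(pmax(x, floor))`.
#' @examples
#' log2_transform(c(8, -5, 1))
#' @export
log2_transform <- function(x, floor = 1) {
  if (floor <= 0) tm_stop("floor must be > 0")
  if (inherits(x, "probe_track")) {
    x$values <- log2(pmax(x$values, floor))
    return(x)
  }
  log2(pmax(x, floor))
}

#' Quantile-normalize replicate columns
#'
#' Forces every column onto the common distribution of across-column mean
#' order statistics, preserving within-column ranks.  Ties receive the mean
#' of the tied order-statistic values (average-rank rule), so the result is
#' invariant to row permutation and the map is idempotent.
#'
#' @param x Numeric matrix with >= 2 columns (or a `"probe_track"`).
#' @return Same shape/class, quantile-normalized.
#' @examples
#' quantile_normalize(cbind(a = c(2, 4, 6), b = c(1, 2, 3)))
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "probe_track")) {
    x$values <- quantile_normalize(x$values)
    return(x)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2L) tm_stop("quantile normalization needs >= 2 columns")
  if (nrow(x) < 1L) tm_stop("quantile normalization needs >= 1 row")
  ref <- rowMeans(apply(x, 2, sort))
  n <- nrow(x)
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    lo <- ref[floor(r)]
    hi <- ref[ceiling(r)]
    out[, j] <- (lo + hi) / 2  # average rank -> mean of flanking order stats
  }
  out
}

#' Scale IP and input channels to a common mean
#'
#' Applies an additive shift in log2 space (multiplicative in linear space)
#' so that both channels' grand means equal the midpoint of the two original
#' grand means.  Within-channel differences between probes are untouched and
#' the grand mean of the pooled values is conserved.
#'
#' @param ip,input Numeric matrices (probes x replicates) or
#'   `"probe_track"`s on the same probe set, log2 scale.
#' @return List with scaled `ip` and `input` of the input classes.
#' @export
scale_to_common_mean <- function(ip, input) {
  ip_tr <- inherits(ip, "probe_track")
  if (ip_tr != inherits(input, "probe_track")) {
    tm_stop("ip and input must both be matrices or both probe_tracks")
  }
  if (ip_tr) {
    same_probes(ip, input, "IP and input tracks")
    sc <- scale_to_common_mean(ip$values, input$values)
    ip$values <- sc$ip
    input$values <- sc$input
    return(list(ip = ip, input = input))
  }
  if (length(ip) == 0L || length(input) == 0L) {
    tm_stop("cannot scale an empty track")
  }
  m_ip <- mean(ip)
  m_in <- mean(input)
  target <- (m_ip + m_in) / 2
  list(ip = ip - (m_ip - target), input = input - (m_in - target))
}

#' Per-probe log ratio of replicate-averaged IP to input
#'
#' @param ip,input `"probe_track"`s on identical probe sets (log2 scale).
#' @return An `"enrichment_track"` with value
#'   `rowMeans(log2 IP) - rowMeans(log2 input)`.
#' @export
log_ratio <- function(ip, input) {
  stopifnot(inherits(ip, "probe_track"), inherits(input, "probe_track"))
  same_probes(ip, input, "IP and input tracks")
  enrichment_track(ip$chrom, ip$positions,
                   rowMeans(ip$values) - rowMeans(input$values))
}

#' Adjust a mark's enrichment track for total H3
#'
#' Subtracts the total-H3 log ratio probe-by-probe, removing nucleosome
#' occupancy and probe-density structure shared with the H3 channel; the
#' result reads as log2 signal relative to H3.
#'
#' @param mark,h3 `"enrichment_track"`s on identical probe sets.
#' @return An `"enrichment_track"` of per-probe differences.
#' @export
h3_adjust <- function(mark, h3) {
  stopifnot(inherits(mark, "enrichment_track"),
            inherits(h3, "enrichment_track"))
  same_probes(mark, h3, "mark and H3 tracks")
  enrichment_track(mark$chrom, mark$positions, mark$value - h3$value)
}

#' Normalize one mark end to end
#'
#' Convenience chain used by the pipeline: log2 transform with flooring,
#' quantile normalization of the replicate columns within each channel,
#' scaling of the two channels to a common mean, then the replicate-mean
#' IP/input log ratio.
#'
#' @param ip_raw,input_raw `"probe_track"`s of linear-scale PM-MM values.
#' @param floor Flooring value passed to [log2_transform()].
#' @return An `"enrichment_track"`.
#' @export
normalize_mark <- function(ip_raw, input_raw, floor = 1) {
  ip <- quantile_normalize(log2_transform(ip_raw, floor))
  input <- quantile_normalize(log2_transform(input_raw, floor))
  sc <- scale_to_common_mean(ip, input)
  log_ratio(sc$ip, sc$input)
}
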