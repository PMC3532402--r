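# Enriched-region detection: moderated probe-level t-statistics, a two-state
# Gaussian HMM decoded by forward-backward, and the gap/run/posterior rules
# that turn per-probe posteriors into regions.

#' Configuration for the two-state HMM region caller
#'
#' Defaults are the published calling rules: probes are combined with a
#' maximal gap of 1000 bp, a minimal run of 200 bp, and a posterior
#' probability cutoff of 0.5.
#'
#' @param max_gap_bp Maximal genomic gap (bp) between seed probes merged into
#'   one region; default 1000.
#' @param min_run_bp Minimal span (bp) of a merged region; default 200.
#' @param posterior_cutoff Posterior probability defining seed probes,
#'   in `[0, 1]`; default 0.5.
#' @param stay_prob_background,stay_prob_enriched Fixed self-transition
#'   probabilities of the background and enriched states; defaults 0.99 and
#'   0.9 (background runs are long, enrichment blocks short).
#' @param em_max_iter,em_tol EM stopping rules for the Gaussian emission
#'   parameters (transitions are not re-estimated).
#' @param variance_shrinkage_weight Weight `w` in `[0, 1]` given to the
#'   genome-wide median pooled variance when moderating per-probe variances;
#'   default 0.5.
#' @return Object of class `"hmm_config"`.
#' @export
hmm_config <- function(max_gap_bp = 1000L, min_run_bp = 200L,
                       posterior_cutoff = 0.5,
                       stay_prob_background = 0.99,
                       stay_prob_enriched = 0.9,
                       em_max_iter = 25L, em_tol = 1e-4,
                       variance_shrinkage_weight = 0.5) {
  if (posterior_cutoff < 0 || posterior_cutoff > 1) {
    tm_stop("posterior_cutoff must be in [0, 1]")
  }
  if (min_run_bp <= 0) tm_stop("min_run_bp must be > 0")
  if (max_gap_bp < 0) tm_stop("max_gap_bp must be >= 0")
  if (variance_shrinkage_weight < 0 || variance_shrinkage_weight > 1) {
    tm_stop("variance_shrinkage_weight must be in [0, 1]")
  }
  structure(list(max_gap_bp = as.integer(max_gap_bp),
                 min_run_bp = as.integer(min_run_bp),
                 posterior_cutoff = posterior_cutoff,
                 stay_prob_background = stay_prob_background,
                 stay_prob_enriched = stay_prob_enriched,
                 em_max_iter = as.integer(em_max_iter),
                 em_tol = em_tol,
                 variance_shrinkage_weight = variance_shrinkage_weight),
            class = "hmm_config")
}

#' Moderated probe-level t-statistics for IP vs input
#'
#' With only two replicates per channel, raw per-probe variances are
#' unstable; the pooled per-probe variance is shrunk toward the genome-wide
#' median pooled variance:
#' `s2 = w * median(pooled) + (1 - w) * pooled`, and
#' `t = (mean_IP - mean_input) / sqrt(s2 * (1/n_IP + 1/n_input))`.
#'
#' @param ip,input `"probe_track"`s (log2 scale, >= 2 replicates each) on
#'   identical probe sets.
#' @param variance_shrinkage_weight Shrinkage weight `w` in `[0, 1]`.
#' @return Numeric vector of finite t-statistics, one per probe.
#' @export
probe_t_statistics <- function(ip, input, variance_shrinkage_weight = 0.5) {
  stopifnot(inherits(ip, "probe_track"), inherits(input, "probe_track"))
  same_probes(ip, input, "IP and input tracks")
  n1 <- ncol(ip$values)
  n2 <- ncol(input$values)
  if (n1 < 2L || n2 < 2L) {
    tm_stop("probe-level t-statistics need >= 2 replicates per channel")
  }
  w <- variance_shrinkage_weight
  row_var <- function(m) rowSums((m - rowMeans(m))^2) / (ncol(m) - 1L)
  pooled <- ((n1 - 1L) * row_var(ip$values) +
               (n2 - 1L) * row_var(input$values)) / (n1 + n2 - 2L)
  s2 <- w * stats::median(pooled) + (1 - w) * pooled
  s2 <- pmax(s2, 1e-12)  # keep t finite on degenerate probes
  (rowMeans(ip$values) - rowMeans(input$values)) /
    sqrt(s2 * (1 / n1 + 1 / n2))
}

# scaled forward-backward for a 2-state HMM with Gaussian emissions.
# A is the 2x2 transition matrix, pi0 the initial distribution, and
# dens the T x 2 emission density matrix.  Returns posteriors and loglik.
forward_backward2 <- function(dens, A, pi0) {
  n <- nrow(dens)
  alpha <- matrix(0, n, 2)
  beta <- matrix(0, n, 2)
  cscale <- numeric(n)
  a <- pi0 * dens[1, ]
  cscale[1] <- sum(a)
  alpha[1, ] <- a / cscale[1]
  a11 <- A[1, 1]; a12 <- A[1, 2]; a21 <- A[2, 1]; a22 <- A[2, 2]
  for (t in 2:n) {
    p1 <- (alpha[t - 1, 1] * a11 + alpha[t - 1, 2] * a21) * dens[t, 1]
    p2 <- (alpha[t - 1, 1] * a12 + alpha[t - 1, 2] * a22) * dens[t, 2]
    s <- p1 + p2
    cscale[t] <- s
    alpha[t, 1] <- p1 / s
    alpha[t, 2] <- p2 / s
  }
  beta[n, ] <- 1
  for (t in (n - 1):1) {
    b1 <- (a11 * dens[t + 1, 1] * beta[t + 1, 1] +
             a12 * dens[t + 1, 2] * beta[t + 1, 2]) / cscale[t + 1]
    b2 <- (a21 * dens[t + 1, 1] * beta[t + 1, 1] +
             a22 * dens[t + 1, 2] * beta[t + 1, 2]) / cscale[t + 1]
    beta[t, 1] <- b1
    beta[t, 2] <- b2
  }
  g <- alpha * beta
  g <- g / rowSums(g)
  list(gamma = g, loglik = sum(log(cscale)))
}

#' Fit a two-state Gaussian HMM to probe-level t-statistics
#'
#' States are background and enriched.  Emission means/SDs are estimated by
#' EM (initialized from probes below/above the 90th percentile of t);
#' transition probabilities are fixed from the configuration, which keeps
#' decoding deterministic and stable on short tracks.  Posteriors of the
#' enriched state come from the forward-backward algorithm.  A degenerate
#' input (all t equal) returns an all-zero posterior rather than an error.
#'
#' @param t_track Numeric vector of probe-level t-statistics (>= 10 probes).
#' @param config An [hmm_config()].
#' @return List: `posterior` (enriched-state probability per probe), `mu`,
#'   `sigma` (length-2 emission parameters, background then enriched),
#'   `loglik`, `n_iter`.
#' @export
fit_two_state_hmm <- function(t_track, config = hmm_config()) {
  stopifnot(inherits(config, "hmm_config"))
  n <- length(t_track)
  if (n < 10L) tm_stop("HMM fitting needs >= 10 probes")
  if (!all(is.finite(t_track))) tm_stop("t-statistics must be finite")
  if (diff(range(t_track)) < 1e-12) {
    return(list(posterior = rep(0, n), mu = rep(t_track[1], 2),
                sigma = c(0, 0), loglik = NA_real_, n_iter = 0L))
  }
  q90 <- stats::quantile(t_track, 0.9, names = FALSE)
  lo <- t_track[t_track < q90]
  hi <- t_track[t_track >= q90]
  if (length(lo) < 2L || length(hi) < 2L) {  # extreme ties around q90
    lo <- sort(t_track)[seq_len(ceiling(n * 0.9))]
    hi <- sort(t_track)[-seq_len(ceiling(n * 0.9))]
  }
  mu <- c(mean(lo), mean(hi))
  sigma <- pmax(c(stats::sd(lo), stats::sd(hi)), 1e-3)
  A <- matrix(c(config$stay_prob_background, 1 - config$stay_prob_background,
                1 - config$stay_prob_enriched, config$stay_prob_enriched),
              2, 2, byrow = TRUE)
  # stationary distribution of the fixed transition matrix
  pi0 <- c(A[2, 1], A[1, 2]) / (A[1, 2] + A[2, 1])
  ll_old <- -Inf
  fb <- NULL
  iter <- 0L
  for (iter in seq_len(config$em_max_iter)) {
    dens <- cbind(stats::dnorm(t_track, mu[1], sigma[1]),
                  stats::dnorm(t_track, mu[2], sigma[2]))
    dens <- pmax(dens, 1e-300)
    fb <- forward_backward2(dens, A, pi0)
    g <- fb$gamma
    wsum <- colSums(g)
    mu_new <- colSums(g * t_track) / wsum
    sd_new <- sqrt(colSums(g * (outer(t_track, mu_new, "-")^2)) / wsum)
    mu <- mu_new
    sigma <- pmax(sd_new, 1e-3)
    if (is.finite(ll_old) &&
        abs(fb$loglik - ll_old) < config$em_tol * (abs(ll_old) + 1)) {
      break
    }
    ll_old <- fb$loglik
  }
  # the enriched state is the one with the larger emission mean
  enr <- which.max(mu)
  list(posterior = fb$gamma[, enr],
       mu = c(mu[-enr], mu[enr]), sigma = c(sigma[-enr], sigma[enr]),
       loglik = fb$loglik, n_iter = iter)
}

#' Combine seed probes into enriched regions under gap/run rules
#'
#' Probes with posterior >= `posterior_cutoff` are seeds.  Consecutive seeds
#' whose genomic gap is at most `max_gap_bp` merge into one region spanning
#' from the first seed position to the last seed position plus one probe
#' spacing; merged regions whose span falls below `min_run_bp` are
#' discarded.
#'
#' @param posteriors Numeric vector in `[0, 1]`, one per probe.
#' @param positions Sorted integer probe positions (0-based).
#' @param config An [hmm_config()].
#' @param chrom Chromosome name recorded in the output.
#' @param probe_spacing Probe spacing in bp; if `NULL`, the median gap
#'   between adjacent probes is used.
#' @return data.frame(chrom, start, end, mean_posterior, n_probes), sorted
#'   and non-overlapping; zero rows if nothing passes.
#' @export
call_regions <- function(posteriors, positions, config = hmm_config(),
                         chrom = "chr1", probe_spacing = NULL) {
  stopifnot(inherits(config, "hmm_config"))
  if (length(posteriors) != length(positions)) {
    tm_stop("posteriors and positions differ in length")
  }
  if (is.unsorted(positions)) tm_stop("positions must be sorted")
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), mean_posterior = numeric(),
                      n_probes = integer(), stringsAsFactors = FALSE)
  seeds <- which(posteriors >= config$posterior_cutoff)
  if (length(seeds) == 0L) return(empty)
  if (is.null(probe_spacing)) {
    probe_spacing <- if (length(positions) > 1L) {
      stats::median(diff(positions))
    } else 1
  }
  sp <- positions[seeds]
  brk <- which(diff(sp) > config$max_gap_bp)
  run_start <- c(1L, brk + 1L)
  run_end <- c(brk, length(sp))
  out <- data.frame(
    chrom = chrom,
    start = sp[run_start],
    end = sp[run_end] + as.integer(probe_spacing),
    mean_posterior = vapply(seq_along(run_start), function(i) {
      mean(posteriors[seeds[run_start[i]:run_end[i]]])
    }, numeric(1)),
    n_probes = run_end - run_start + 1L,
    stringsAsFactors = FALSE
  )
  out <- out[out$end - out$start >= config$min_run_bp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize enriched-region sizes
#'
#' @param regions Region table from [call_regions()].
#' @param histogram_breaks Bin edges (bp) for the length histogram.
#' @return List: `n_regions`, `fraction_gt_400bp` (strictly greater than
#'   400 bp; `NA` if no regions), `n_gt_1kbp`, `total_bp`, and `histogram`
#'   (named counts per length bin).
#' @export
region_size_summary <- function(regions,
                                histogram_breaks = c(0, 200, 400, 600, 800,
                                                     1000, 2000, 5000, Inf)) {
  check_regions(regions)
  len <- regions$end - regions$start
  h <- table(cut(len, histogram_breaks, right = TRUE))
  list(
    n_regions = nrow(regions),
    fraction_gt_400bp = if (length(len) > 0L) mean(len > 400) else NA_real_,
    n_gt_1kbp = sum(len > 1000),
    total_bp = sum(len),
    histogram = stats::setNames(as.integer(h), names(h))
  )
}

#' Windowed percent coverage of enriched regions
#'
#' Splits each chromosome into consecutive non-overlapping windows and
#' reports `100 * covered bases / window_bp` per window; regions straddling
#' a window boundary contribute their bases to each side.  The terminal
#' partial window is still divided by `window_bp`.
#'
#' @param regions Region table (0-based half-open, non-overlapping).
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param window_bp Window size in bp, default 20000 (coverage per 20 kb).
#' @return data.frame(chrom, start, end, pct_coverage).
#' @export
coverage_track <- function(regions, chrom_lengths, window_bp = 20000L) {
  check_regions(regions)
  out <- lapply(names(chrom_lengths), function(chr) {
    len <- chrom_lengths[[chr]]
    starts <- seq(0, len - 1, by = window_bp)
    ends <- pmin(starts + window_bp, len)
    r <- regions[regions$chrom == chr, , drop = FALSE]
    covered <- numeric(length(starts))
    if (nrow(r) > 0L) {
      cov <- IRanges::coverage(
        IRanges::IRanges(start = pmax(r$start, 0) + 1L,
                         end = pmin(r$end, len)),
        width = len)
      v <- IRanges::Views(cov, start = starts + 1L, end = ends)
      covered <- IRanges::viewSums(v)
    }
    data.frame(chrom = chr, start = as.integer(starts),
               end = as.integer(ends),
               pct_coverage = 100 * covered / window_bp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
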