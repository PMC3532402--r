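# Independent oracles and small fixture builders shared across tests.
# Each oracle is deliberately written with a different algorithmic shape
# than the implementation it checks.

# Brute-force region caller: for every seed probe, expand the maximal run
# containing it by walking left and right while consecutive seed gaps stay
# within max_gap; collect unique runs, then apply the min-run rule.
oracle_call_regions <- function(posteriors, positions, cutoff = 0.5,
                                max_gap = 1000, min_run = 200, spacing) {
  seeds <- which(posteriors >= cutoff)
  runs <- list()
  for (i in seeds) {
    lo <- i
    while (TRUE) {
      prev <- seeds[seeds < lo]
      if (length(prev) == 0L) break
      p <- max(prev)
      if (positions[lo] - positions[p] <= max_gap) lo <- p else break
    }
    hi <- i
    while (TRUE) {
      nxt <- seeds[seeds > hi]
      if (length(nxt) == 0L) break
      p <- min(nxt)
      if (positions[p] - positions[hi] <= max_gap) hi <- p else break
    }
    runs[[paste(lo, hi)]] <- c(lo, hi)
  }
  out <- data.frame(start = integer(), end = integer(),
                    mean_posterior = numeric(), n_probes = integer())
  for (r in runs) {
    members <- seeds[seeds >= r[1] & seeds <= r[2]]
    start <- positions[r[1]]
    end <- positions[r[2]] + spacing
    if (end - start >= min_run) {
      out <- rbind(out, data.frame(
        start = start, end = end,
        mean_posterior = mean(posteriors[members]),
        n_probes = length(members)))
    }
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Quadratic all-pairs neighbor-gap oracle for the gene-spacing filter.
oracle_spaced_genes <- function(genes, min5 = 350, min3 = 150) {
  keep <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    left <- Inf
    right <- Inf
    for (j in seq_len(nrow(genes))) {
      if (j == i || genes$chrom[j] != g$chrom) next
      if (genes$start[j] < g$start) {
        left <- min(left, g$start - genes$end[j])
      } else if (genes$start[j] > g$start) {
        right <- min(right, genes$start[j] - g$end)
      }
    }
    if (g$strand == "+") {
      keep[i] <- left >= min5 && right >= min3
    } else {
      keep[i] <- right >= min5 && left >= min3
    }
  }
  genes[keep, , drop = FALSE]
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Random non-overlapping gene layout for property tests.
make_genes <- function(n, seed, chrom = "chr1", min_len = 100,
                       max_len = 2000, max_gap = 1500) {
  withr::with_seed(seed, {
    len <- sample(min_len:max_len, n, replace = TRUE)
    gap <- sample(0:max_gap, n, replace = TRUE)
    start <- cumsum(gap) + cumsum(c(0, len[-n]))
    data.frame(
      gene_id = sprintf("T%04d", seq_len(n)),
      chrom = chrom, start = start, end = start + len,
      strand = sample(c("+", "-"), n, replace = TRUE),
      gene_type = sample(c("protein_coding", "transposon", "pseudogene"),
                         n, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
      te_class = NA_character_, stringsAsFactors = FALSE)
  }) -> g
  g$te_class[g$gene_type == "transposon"] <- "LTR/Gypsy"
  g
}

# Hand-rolled sort-and-average quantile normalization (tie-free inputs).
oracle_quantile_normalize <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) out[order(x[, j]), j] <- ref
  out
}
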