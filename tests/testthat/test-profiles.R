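test_that("gene-spacing filter applies the 350/150 bp rules", {
  # single gene on a chromosome: no neighbors, included
  lone <- make_genes(1, seed = 1)
  expect_equal(nrow(select_spaced_genes(lone)), 1L)
  # two plus-strand genes with a 100-bp gap: downstream fails 5', upstream
  # fails 3' (100 < 150)
  g2 <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                   start = c(0L, 1100L), end = c(1000L, 2000L),
                   strand = "+", gene_type = "protein_coding",
                   te_class = NA_character_)
  expect_equal(nrow(select_spaced_genes(g2)), 0L)
  # widen the gap to 400 bp: both pass
  g2$start[2] <- 1400L
  expect_equal(select_spaced_genes(g2)$gene_id, c("a", "b"))
  # minus-strand gene swaps which side is 5'
  g2$strand <- c("+", "-")
  g2$start[2] <- 1200L   # gap 200: >= 150 (3' of a, 3' of b)... both sides
  g2$end[2] <- 2000L
  # gene b: 5' side is its right (chromosome end, Inf), 3' side is the gap
  expect_true("b" %in% select_spaced_genes(g2)$gene_id)
})

test_that("gene-spacing filter matches the quadratic oracle on random
           layouts", {
  for (s in 1:40) {
    withr::with_seed(s, {
      n <- sample(2:25, 1)
      len <- sample(100:1500, n, replace = TRUE)
      gap <- sample(0:600, n, replace = TRUE)
      start <- cumsum(gap) + cumsum(c(0, len[-n]))
      g <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
                      start = start, end = start + len,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      gene_type = "protein_coding",
                      te_class = NA_character_)
    })
    expect_equal(select_spaced_genes(g)$gene_id,
                 oracle_spaced_genes(g)$gene_id)
  }
})

make_track <- function(value_fun, from = -500, to = 2500, spacing = 10,
                       chrom = "chr1", offset = 0) {
  pos <- seq(from, to, by = spacing) + offset
  enrichment_track(chrom, pos, value_fun(pos))
}

test_that("positional profiles have the 15-bin schema and honour windows", {
  gene <- data.frame(gene_id = "g1", chrom = "chr1", start = 0L,
                     end = 1000L, strand = "+",
                     gene_type = "protein_coding", te_class = NA_character_)
  # constant track -> every bin equals the constant
  tr <- make_track(function(p) rep(2.5, length(p)))
  prof <- positional_profile(tr, gene)
  expect_length(prof, 15L)
  expect_named(prof, PROFILE_BINS)
  expect_true(all(prof == 2.5))
  # hand-binned oracle: value = position, probes every 10 bp
  tr2 <- make_track(function(p) as.numeric(p))
  prof2 <- positional_profile(tr2, gene)
  # promoter bin P1 = [-350, -250): probes -350..-260 -> mean -305
  expect_equal(unname(prof2["P1"]), mean(seq(-350, -260, 10)))
  # TSS bin [-49, 50): probes -40..40
  expect_equal(unname(prof2["TSS"]), mean(seq(-40, 40, 10)))
  # body bin B1 = [50, 150): probes 50..140
  expect_equal(unname(prof2["B1"]), mean(seq(50, 140, 10)))
  # 3' end bin E = [950, 1050); flank F = [1050, 1150)
  expect_equal(unname(prof2["E"]), mean(seq(950, 1040, 10)))
  expect_equal(unname(prof2["F"]), mean(seq(1050, 1140, 10)))
  # empty windows are NA
  sparse <- enrichment_track("chr1", c(0L, 500L), c(1, 2))
  prof3 <- positional_profile(sparse, gene)
  expect_true(is.na(prof3["P1"]))
  # short gene is skipped with a warning
  tiny <- gene
  tiny$end <- 10L
  expect_warning(res <- positional_profile(tr, tiny), "skipped")
  expect_null(res)
})

test_that("profiles are strand-symmetric and translation-invariant", {
  withr::with_seed(61, vals <- rnorm(501))
  G <- 5000L
  pos <- seq(0L, G, by = 10L)
  tr <- enrichment_track("chr1", pos, vals)
  gene <- data.frame(gene_id = "g", chrom = "chr1", start = 1000L,
                     end = 2400L, strand = "+",
                     gene_type = "protein_coding", te_class = NA_character_)
  p_fwd <- positional_profile(tr, gene)
  # reflect the genome about its last base (p' = G - 1 - p) and flip the
  # strand: transcription-oriented distances are unchanged, so the profile
  # must be identical bin for bin
  tr_ref <- enrichment_track("chr1", sort(G - 1L - pos), rev(vals))
  gene_ref <- gene
  gene_ref$start <- G - gene$end
  gene_ref$end <- G - gene$start
  gene_ref$strand <- "-"
  expect_equal(positional_profile(tr_ref, gene_ref), p_fwd)
  # translation by a constant
  shift <- 70000L
  tr_sh <- enrichment_track("chr1", pos + shift, vals)
  gene_sh <- gene
  gene_sh$start <- gene$start + shift
  gene_sh$end <- gene$end + shift
  expect_equal(positional_profile(tr_sh, gene_sh), p_fwd)
})

test_that("group means respect missing bins and reject empty groups", {
  m <- rbind(a = rep(1, 15), b = rep(3, 15), c = rep(5, 15))
  colnames(m) <- PROFILE_BINS
  gm <- group_mean_profile(m, c("x", "x", "y"))
  expect_equal(unname(gm["x", ]), rep(2, 15))
  expect_equal(unname(gm["y", ]), rep(5, 15))
  # identical profiles: mean equals each
  gm1 <- group_mean_profile(m[c(1, 1), ], c("z", "z"))
  expect_equal(unname(gm1["z", ]), rep(1, 15))
  # missing bin excluded from the mean; all-missing bin stays NA
  m2 <- m
  m2["a", "B3"] <- NA
  gm2 <- group_mean_profile(m2, c("x", "x", "y"))
  expect_equal(unname(gm2["x", "B3"]), 3)
  m3 <- m
  m3[, "F"] <- NA
  expect_true(all(is.na(group_mean_profile(m3, c("x", "x", "x"))[, "F"])))
  expect_error(group_mean_profile(m, factor(c("x", "x", "x"),
                                            levels = c("x", "gone"))),
               "gone")
  # random profiles vs direct arithmetic
  withr::with_seed(62, r <- matrix(rnorm(10 * 15), 10, 15))
  grp <- rep(c("p", "q"), each = 5)
  gmr <- group_mean_profile(r, grp)
  expect_equal(unname(gmr["p", ]), colMeans(r[1:5, ]))
})

test_that("decile assignment splits evenly with ties broken by gene id", {
  m <- matrix(0, 20, 15, dimnames = list(sprintf("g%02d", 1:20),
                                         PROFILE_BINS))
  expr <- setNames(rep(c(1, 2), each = 10), rownames(m))
  d <- decile_profiles(m, expr)
  expect_equal(as.integer(table(d$decile)), rep(2L, 10))
  # ties resolved by stable gene-id order: g01 precedes g02
  expect_lte(d$decile["g01"], d$decile["g02"])
  expect_identical(d$decile,
                   decile_profiles(m[sample(1:20), , drop = FALSE],
                                   expr)$decile[names(d$decile)])
  expect_error(decile_profiles(m[1:5, ], expr[1:5]), ">= 10")
  # remainder goes to the lower deciles
  m23 <- matrix(0, 23, 15, dimnames = list(sprintf("h%02d", 1:23),
                                           PROFILE_BINS))
  d23 <- decile_profiles(m23, setNames(1:23, rownames(m23)))
  expect_equal(as.integer(table(d23$decile)), c(3L, 3L, 3L, rep(2L, 7)))
})

test_that("planted expression-depletion gradient shows up across deciles", {
  # higher expression -> deeper gene-body depletion
  n <- 50
  ids <- sprintf("g%02d", 1:n)
  expr <- setNames(seq_len(n), ids)
  m <- matrix(0.5, n, 15, dimnames = list(ids, PROFILE_BINS))
  withr::with_seed(63, noise <- matrix(rnorm(n * 15, 0, 0.05), n, 15))
  body <- PROFILE_BINS[5:13]
  m[, body] <- m[, body] - outer(expr / n, rep(1, 9))
  m <- m + noise
  d <- decile_profiles(m, expr)
  expect_lt(mean(d$profiles["decile10", body]),
            mean(d$profiles["decile01", body]))
})

test_that("relative profiles subtract bin-wise and propagate missing", {
  a <- setNames(rnorm(15), PROFILE_BINS)
  expect_equal(relative_profile(a, a), setNames(rep(0, 15), PROFILE_BINS))
  b <- a
  b[] <- NA_real_
  expect_true(all(is.na(relative_profile(a, b))))
  withr::with_seed(64, {
    x <- setNames(rnorm(15), PROFILE_BINS)
    y <- setNames(rnorm(15), PROFILE_BINS)
  })
  expect_equal(relative_profile(x, y), x - y)
  wrong <- setNames(rnorm(15), rev(PROFILE_BINS))
  expect_error(relative_profile(x, wrong), "labels")
})
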