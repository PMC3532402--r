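# Planted chromatin-state archetypes shared by the clustering and
# acceptance tests: the four transposon-gene profile shapes
# (5'-peaked me2, me3-only, uniform me2, 3'-peaked me2).
te_archetypes <- function() {
  ramp_down <- c(rep(2, 4), seq(2, 0, length.out = 9), 0, 0)
  ramp_up <- rev(ramp_down)
  flat <- rep(1.5, 15)
  zero <- rep(0, 15)
  list(
    TE1 = list(me2 = ramp_down, me3 = zero),
    TE2 = list(me2 = zero, me3 = flat + 1),
    TE3 = list(me2 = flat, me3 = zero),
    TE4 = list(me2 = ramp_up, me3 = zero)
  )
}

planted_profiles <- function(n_per, noise_sd, seed) {
  arch <- te_archetypes()
  ids <- sprintf("g%03d", seq_len(n_per * 4))
  truth <- rep(names(arch), each = n_per)
  withr::with_seed(seed, {
    sets <- lapply(c("me2", "me3"), function(m) {
      mu <- do.call(rbind, lapply(arch, function(a) a[[m]]))
      x <- mu[rep(1:4, each = n_per), ] +
        matrix(rnorm(n_per * 4 * 15, 0, noise_sd), n_per * 4, 15)
      dimnames(x) <- list(ids, PROFILE_BINS)
      x
    })
  })
  names(sets) <- c("me2", "me3")
  list(sets = sets, truth = truth, ids = ids)
}

# The gene-type counts printed in the published gene-type representation
# table, used as *inputs* by the worked-example acceptance checks.
published_gene_counts <- function() {
  list(
    entire = c(protein_coding = 27025, transposon = 3900, pseudogene = 859,
               tRNA = 631, other_RNA = 326, miRNA = 174, snoRNA = 71,
               snRNA = 13, rRNA = 4),
    me2 = c(protein_coding = 991, transposon = 580, pseudogene = 24,
            tRNA = 0, other_RNA = 11, miRNA = 0, snoRNA = 0,
            snRNA = 0, rRNA = 0),
    me3 = c(protein_coding = 7090, transposon = 225, pseudogene = 287,
            tRNA = 5, other_RNA = 54, miRNA = 65, snoRNA = 2,
            snRNA = 1, rRNA = 0)
  )
}

# Rebuild a gene universe + enrichment flags realizing the printed counts.
published_universe <- function(mark = c("me2", "me3")) {
  mark <- match.arg(mark)
  cn <- published_gene_counts()
  genes <- data.frame(
    gene_id = sprintf("g%05d", seq_len(sum(cn$entire))),
    chrom = "chr1", start = 0L, end = 0L, strand = "+",
    gene_type = rep(names(cn$entire), cn$entire),
    te_class = NA_character_, stringsAsFactors = FALSE)
  genes$start <- seq(0L, by = 200L, length.out = nrow(genes))
  genes$end <- genes$start + 100L
  flags <- unlist(lapply(names(cn$entire), function(ty) {
    f <- rep(FALSE, cn$entire[[ty]])
    f[seq_len(cn[[mark]][[ty]])] <- TRUE
    f
  }))
  list(genes = genes, flags = flags)
}
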