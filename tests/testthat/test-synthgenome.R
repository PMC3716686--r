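# Synthetic-genome simulator: mitochondrial genomes, planted insertions,
# truth-ledger guarantees, and determinism.

test_that("mitochondrial genome honours lengths, topology, and ITRs", {
  # two linear chromosomes totalling a hydrozoan-like 15,880 bp
  cfg <- sim_config(seed = 1, mito_topology = "linear",
                    n_mito_chromosomes = 2L,
                    mito_lengths = c(8194L, 7686L), itr_length = 150L)
  mito <- generate_mito_genome(cfg)
  expect_equal(unname(Biostrings::width(mito$seq)), c(8194L, 7686L))
  expect_equal(mito$total_length, 15880L)
  # both chromosomes carry the identical ITR at each end (inverted at 3')
  s1 <- as.character(mito$seq[[1]]); s2 <- as.character(mito$seq[[2]])
  itr <- substr(s1, 1, 150)
  expect_equal(substr(s2, 1, 150), itr)
  expect_equal(substr(s1, 8194 - 149, 8194), revcomp_chr(itr))
  expect_equal(substr(s2, 7686 - 149, 7686), revcomp_chr(itr))

  # a single circular anthozoan-like molecule has no ITR
  cfg2 <- sim_config(seed = 1, mito_topology = "circular",
                     n_mito_chromosomes = 1L, mito_lengths = 16389L,
                     itr_length = 0L)
  mito2 <- generate_mito_genome(cfg2)
  expect_equal(length(mito2$seq), 1L)
  expect_equal(mito2$total_length, 16389L)
  expect_equal(mito2$itr_length, 0L)

  # degenerate ITR of length 0: ends of long random chromosomes differ
  cfg3 <- sim_config(seed = 2, itr_length = 0L)
  mito3 <- generate_mito_genome(cfg3)
  a <- as.character(mito3$seq[[1]]); b <- as.character(mito3$seq[[2]])
  expect_false(substr(a, 1, 100) == substr(b, 1, 100))
})

test_that("the annotation covers the full mitochondrial gene complement", {
  cfg <- sim_config(seed = 4, mito_topology = "circular",
                    n_mito_chromosomes = 1L, mito_lengths = 16389L,
                    itr_length = 0L, intron_in_nd5 = TRUE)
  mito <- generate_mito_genome(cfg)
  ann <- mito$annotation
  genes <- ann[ann$type == "gene", ]
  expect_gte(sum(genes$gene %in% c("ND1", "ND2", "ND3", "ND4", "ND4L",
                                   "ND5", "ND6", "COX1", "COX2", "COX3",
                                   "ATP6", "ATP8", "CYTB")), 13)
  expect_equal(sum(genes$gene %in% c("s-rRNA", "l-rRNA")), 2)
  expect_gte(sum(grepl("^tRNA", genes$gene)), 2)
  # the ND5 intron is recorded and lies inside the ND5 span
  expect_false(is.null(mito$nd5_intron))
  nd5 <- genes[genes$gene == "ND5", ]
  expect_gte(mito$nd5_intron$start, nd5$start)
  expect_lte(mito$nd5_intron$end, nd5$end)
})

test_that("invalid configurations are refused with configuration errors", {
  expect_error(sim_config(mito_topology = "circular",
                          n_mito_chromosomes = 2L,
                          mito_lengths = c(8000L, 8000L)),
               "configuration error")
  expect_error(sim_config(mito_lengths = c(400L, 500L)), "1,000 bp")
  expect_error(sim_config(itr_length = 5000L), "itr_length")
  expect_error(sim_config(n_insertions = 5L, n_intronic = 10L),
               "configuration error")
  expect_error(sim_config(n_insertions = 5L,
                          duplication_spec = list(c(3L, 2L))),
               "configuration error")
  expect_error(sim_config(divergence_dist = list(min = 0, max = 0.5,
                                                 indel_frac = 0.1)),
               "divergence")
})

test_that("zero-divergence insertions are exact substrings of the nuclear genome", {
  cfg <- sim_config(seed = 9, nuclear_length = 120000L, n_scaffolds = 1L,
                    n_genes = 4L, n_insertions = 5L,
                    divergence_dist = list(min = 0, max = 0, indel_frac = 0))
  mito <- generate_mito_genome(cfg)
  g <- generate_nuclear_genome(cfg, mito)
  for (i in seq_len(nrow(g$ledger))) {
    row <- g$ledger[i, ]
    planted <- as.character(Biostrings::subseq(
      g$nuclear[[row$nuclear_scaffold]], row$nuclear_start, row$nuclear_end))
    src <- as.character(Biostrings::subseq(
      mito$seq[[row$mito_chromosome]], row$mito_start, row$mito_end))
    if (row$strand == "-") src <- revcomp_chr(src)
    expect_identical(planted, src)
  }
})

test_that("identical seed and config give byte-identical outputs", {
  cfg <- sim_config(seed = 7, nuclear_length = 150000L, n_genes = 6L,
                    n_insertions = 10L,
                    est_spec = c(pure_mito = 2L, chimeric_internal = 1L))
  run <- function() {
    m <- generate_mito_genome(cfg)
    g <- generate_nuclear_genome(cfg, m)
    e <- generate_ests(cfg, g, m)
    list(m = as.character(m$seq), n = as.character(g$nuclear),
         led = g$ledger, est = as.character(e$ests))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$m, r2$m)
  expect_identical(r1$n, r2$n)
  expect_identical(r1$led, r2$led)
  expect_identical(r1$est, r2$est)
})

test_that("ledger intervals are in-bounds, non-overlapping, and complete", {
  res <- shared_sim()
  led <- res$genome$ledger
  widths <- setNames(Biostrings::width(res$genome$nuclear),
                     names(res$genome$nuclear))
  expect_true(all(led$nuclear_start >= 1))
  expect_true(all(led$nuclear_end <= widths[led$nuclear_scaffold]))
  # non-overlap within each scaffold
  for (sc in unique(led$nuclear_scaffold)) {
    l <- led[led$nuclear_scaffold == sc, ]
    l <- l[order(l$nuclear_start), ]
    if (nrow(l) > 1) {
      expect_true(all(l$nuclear_start[-1] > l$nuclear_end[-nrow(l)]))
    }
  }
  # completeness by reconstruction: removing every ledger interval from the
  # genome leaves exactly the original background length
  ins_bp <- sum(led$nuclear_end - led$nuclear_start + 1)
  expect_equal(sum(widths) - ins_bp, res$genome$config$nuclear_length)
})

test_that("duplication families in the ledger match the requested spec", {
  # scaled version of a many-family breakdown: sizes 2, 3, and 6
  cfg <- sim_config(seed = 13, nuclear_length = 400000L, n_genes = 8L,
                    n_insertions = 40L,
                    duplication_spec = list(c(2L, 5L), c(3L, 2L), c(6L, 1L)))
  mito <- generate_mito_genome(cfg)
  g <- generate_nuclear_genome(cfg, mito)
  fam <- table(g$ledger$family_id[!is.na(g$ledger$family_id)])
  expect_equal(sum(fam >= 2), 8L) # 5 + 2 + 1 families
  expect_equal(sort(as.integer(fam)), sort(c(rep(2L, 5), rep(3L, 2), 6L)))
  # members of one family share the mitochondrial origin exactly
  led <- g$ledger
  for (f in names(fam)) {
    m <- led[!is.na(led$family_id) & led$family_id == f, ]
    expect_equal(length(unique(m$mito_start)), 1L)
    expect_equal(length(unique(m$mito_end)), 1L)
    expect_gte(length(unique(paste(m$nuclear_scaffold, m$nuclear_start))),
               nrow(m))
  }
})

test_that("realized substitution rates calibrate to the configured divergence", {
  cfg <- sim_config(seed = 31, nuclear_length = 500000L, n_genes = 5L,
                    n_insertions = 25L,
                    insertion_length_dist = list(min = 500L, max = 2000L,
                                                 shape = "uniform"),
                    divergence_dist = list(min = 0.02, max = 0.12,
                                           indel_frac = 0))
  mito <- generate_mito_genome(cfg)
  g <- generate_nuclear_genome(cfg, mito)
  led <- g$ledger
  len <- led$mito_end - led$mito_start + 1
  ok <- len >= 500
  rate <- led$n_subst[ok] / len[ok]
  sd2 <- 2 * sqrt(led$divergence[ok] * (1 - led$divergence[ok]) / len[ok])
  expect_true(all(abs(rate - led$divergence[ok]) <= sd2 + 1e-12))
})

test_that("intronic insertions sit inside introns with one orientation per gene", {
  res <- shared_sim()
  led <- res$genome$ledger
  intr <- led[!is.na(led$host_feature) & grepl("^intron", led$host_feature), ]
  expect_equal(nrow(intr), 3L)
  ex <- res$genome$exons
  for (i in seq_len(nrow(intr))) {
    e <- ex[ex$gene_id == intr$host_gene[i], ]
    # inside the gene but not touching any exon
    expect_true(all(intr$nuclear_end[i] < e$final_start |
                      intr$nuclear_start[i] > e$final_end))
  }
  # single orientation per host gene
  for (gid in unique(intr$host_gene)) {
    expect_equal(length(unique(intr$strand[intr$host_gene == gid])), 1L)
  }
})

test_that("EST construction matches the requested classes", {
  res <- shared_sim()
  est <- res$ests
  expect_equal(table(est$truth$class)[["pure_mito"]], 3L)
  expect_equal(table(est$truth$class)[["chimeric_utr5"]], 2L)
  expect_equal(table(est$truth$class)[["chimeric_internal"]], 2L)
  expect_equal(table(est$truth$class)[["plain_nuclear"]], 2L)
  # pure-mito ESTs align to the mitochondrial genome over >= 95% of length
  p <- scoring_params()
  for (id in est$truth$est_id[est$truth$class == "pure_mito"]) {
    h <- filter_hits(search_hits(est$ests[id], res$mito$seq, p))
    cov <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(h$qstart, h$qend))))
    expect_gte(cov / Biostrings::width(est$ests[id]), 0.95)
  }
  # chimeric 5'-UTR ESTs contain one mt block plus a block from the host
  # gene's first exon neighbourhood (verified by aligning back)
  for (id in est$truth$est_id[est$truth$class == "chimeric_utr5"]) {
    hm <- filter_hits(search_hits(est$ests[id], res$mito$seq, p))
    expect_gte(nrow(hm), 1)
    L <- Biostrings::width(est$ests[id])
    cov <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(hm$qstart, hm$qend))))
    expect_lt(cov / L, 0.95) # a substantial non-mito block remains
  }
  # empty spec gives empty output
  cfg0 <- sim_config(seed = 5, nuclear_length = 60000L, n_genes = 2L,
                     n_insertions = 2L)
  m0 <- generate_mito_genome(cfg0)
  g0 <- generate_nuclear_genome(cfg0, m0)
  e0 <- generate_ests(cfg0, g0, m0)
  expect_equal(length(e0$ests), 0L)
  expect_equal(nrow(e0$truth), 0L)
})
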