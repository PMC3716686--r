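# Gene-density classification and in-gene localization.

toy_numts <- function(start, end, scaffold = "sc1", strand = "+") {
  data.frame(numt_id = sprintf("NUMT_%04d", seq_along(start)),
             nuclear_scaffold = scaffold, nuclear_start = start,
             nuclear_end = end, strand = strand, stringsAsFactors = FALSE)
}

test_that("density categories follow the 10-kb window rule", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), scaffold = "sc1",
                      start = c(20000, 22000, 24000),
                      end = c(20900, 22900, 24900),
                      stringsAsFactors = FALSE)
  # no gene within 5 kb on either side
  d0 <- classify_density(toy_numts(50000, 50100), genes)
  expect_equal(d0$density, "non_genic")
  expect_equal(d0$genes_in_window, 0L)
  # exactly 2 genes: low density; 3 genes: high density
  d2 <- classify_density(toy_numts(17000, 17100), genes)   # g1, g2 in reach
  expect_equal(d2$genes_in_window, 2L)
  expect_equal(d2$density, "low_density")
  d3 <- classify_density(toy_numts(22000, 22100), genes)
  expect_equal(d3$genes_in_window, 3L)
  expect_equal(d3$density, "high_density")
  # gene ending exactly one base before the window start is excluded
  gedge <- data.frame(gene_id = "g", scaffold = "sc1",
                      start = 1000, end = 4999, stringsAsFactors = FALSE)
  expect_equal(classify_density(toy_numts(10000, 10100), gedge,
                                10000L)$genes_in_window, 0L)
  gedge$end <- 5000
  expect_equal(classify_density(toy_numts(10000, 10100), gedge,
                                10000L)$genes_in_window, 1L)
})

test_that("interval-index density equals a brute-force scan on large toy annotations", {
  set.seed(55)
  n_genes <- 1000
  gs <- sample.int(990000, n_genes)
  genes <- data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
                      scaffold = "sc1", start = gs,
                      end = gs + sample(500:5000, n_genes, TRUE),
                      stringsAsFactors = FALSE)
  ns <- sample.int(990000, 200)
  numts <- toy_numts(ns, ns + sample(100:2000, 200, TRUE))
  d <- classify_density(numts, genes)
  brute <- vapply(seq_len(nrow(numts)), function(i) {
    brute_density_count(numts$nuclear_start[i], numts$nuclear_end[i],
                        genes$start, genes$end)
  }, 0L)
  expect_identical(d$genes_in_window, brute)
  expect_identical(d$density,
                   ifelse(brute == 0, "non_genic",
                          ifelse(brute <= 2, "low_density", "high_density")))
})

test_that("in-gene localization follows exon dominance and intron numbering", {
  gm <- list(gene_id = "g1", strand = "+",
             exons = data.frame(start = c(1000, 3000), end = c(1500, 3600)))
  # wholly inside the only intron
  loc <- locate_in_gene(toy_numts(1700, 2500)[1, ], gm)
  expect_equal(loc$feature, "intron_1")
  expect_true(loc$same_orientation)
  # straddling an exon boundary: exon dominates
  expect_equal(locate_in_gene(toy_numts(1400, 1900)[1, ], gm)$feature,
               "exon")
  # outside the gene model entirely
  expect_equal(locate_in_gene(toy_numts(5000, 5100)[1, ], gm)$feature,
               "intergenic")
  # UTR annotation
  gmu <- c(gm, list(utr5 = c(700, 999)))
  expect_equal(locate_in_gene(toy_numts(800, 950)[1, ], gmu)$feature, "utr5")
  # malformed model with overlapping exons
  bad <- list(strand = "+",
              exons = data.frame(start = c(100, 300), end = c(400, 600)))
  expect_error(locate_in_gene(toy_numts(1, 10)[1, ], bad), "annotation error")
})

test_that("minus-strand intron numbering matches a coordinate-reversal oracle", {
  set.seed(66)
  for (rep_i in 1:20) {
    ne <- sample(3:6, 1)
    ew <- sample(100:300, ne, TRUE)
    iw <- sample(300:1000, ne - 1, TRUE)
    starts <- cumsum(c(1000, head(ew + c(iw, 0), -1)))
    ex <- data.frame(start = starts, end = starts + ew - 1L)
    k <- sample(ne - 1, 1) # pick intron k in genomic order
    p <- ex$end[k] + 50L
    numt <- toy_numts(p, p + 100L)[1, ]
    gm_minus <- list(strand = "-", exons = ex)
    got <- locate_in_gene(numt, gm_minus)$feature
    # oracle: mirror all coordinates so the gene reads left-to-right, then
    # count introns on the mirrored plus strand
    M <- max(ex$end) + 1000L
    exm <- data.frame(start = M - ex$end, end = M - ex$start)
    exm <- exm[order(exm$start), ]
    numtm <- toy_numts(M - (p + 100L), M - p)[1, ]
    gm_plus <- list(strand = "+", exons = exm)
    expect_equal(got, locate_in_gene(numtm, gm_plus)$feature)
  }
})

test_that("every NUMT gets exactly one density category and one feature", {
  res <- shared_sim()
  ctx <- res$context
  expect_equal(nrow(ctx), nrow(res$numts))
  expect_true(all(ctx$density %in% c("non_genic", "low_density",
                                     "high_density")))
  expect_true(all(grepl("^(intron_[0-9]+|exon|utr5|utr3|intergenic)$",
                        ctx$feature)))
  # density/count consistency
  expect_true(all((ctx$genes_in_window == 0) == (ctx$density == "non_genic")))
  # host gene set exactly when the feature is genic
  expect_true(all(is.na(ctx$host_gene) == (ctx$feature == "intergenic")))
})

test_that("intronic placements are recovered exactly at zero divergence", {
  cfg <- sim_config(seed = 17, nuclear_length = 250000L, n_scaffolds = 1L,
                    n_genes = 10L, n_insertions = 8L, n_intronic = 4L,
                    divergence_dist = list(min = 0, max = 0, indel_frac = 0))
  mito <- generate_mito_genome(cfg)
  genome <- generate_nuclear_genome(cfg, mito)
  p <- scoring_params()
  numts <- call_numts(filter_hits(search_hits(mito, genome$nuclear, p)))
  ctx <- classify_context(numts, genome)
  led <- genome$ledger
  intr <- led[!is.na(led$host_feature) & grepl("^intron", led$host_feature), ]
  expect_equal(nrow(intr), 4L)
  for (i in seq_len(nrow(intr))) {
    # the call recovering this insertion (reciprocal overlap >= 90%; the
    # extension may overshoot the planted edge by a base or two)
    inter <- pmin(numts$nuclear_end, intr$nuclear_end[i]) -
      pmax(numts$nuclear_start, intr$nuclear_start[i]) + 1
    plen <- intr$nuclear_end[i] - intr$nuclear_start[i] + 1
    hit <- which(numts$nuclear_scaffold == intr$nuclear_scaffold[i] &
                   inter / plen >= 0.9 & inter / numts$length >= 0.9)
    expect_equal(length(hit), 1L)
    expect_equal(ctx$host_gene[hit], intr$host_gene[i])
    expect_equal(ctx$feature[hit], intr$host_feature[i])
  }
})
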