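# Seed-and-extend engine, the exact Smith-Waterman oracle, and circular
# topology support.

test_that("Smith-Waterman oracle handles the elementary cases", {
  p <- scoring_params()
  # identical sequences: all-match alignment
  sw <- smith_waterman("ACGT", "ACGT", p)
  expect_equal(sw$score, 4)
  expect_equal(sw$alignment, c("ACGT", "ACGT"))

  # ACGT vs TTTT at +1/-2: a single T-T match is optimal (exhaustively,
  # any longer local alignment pays more in mismatches than it gains)
  sw <- smith_waterman("ACGT", "TTTT", p)
  expect_equal(sw$score, 1)
  expect_equal(sw$alignment, c("T", "T"))

  # empty input
  expect_equal(smith_waterman("", "ACGT", p)$score, 0)

  # size cap
  expect_error(smith_waterman(strrep("A", 4000), strrep("A", 4000), p),
               "too large")
})

test_that("oracle score is symmetric in its arguments", {
  p <- scoring_params()
  set.seed(101)
  for (i in 1:50) {
    a <- rand_dna(sample(20:60, 1))
    b <- rand_dna(sample(20:60, 1))
    expect_identical(smith_waterman(a, b, p)$score,
                     smith_waterman(b, a, p)$score)
  }
})

test_that("self-alignment of a fixed 100-mer yields one full-length identity hit", {
  set.seed(5)
  q <- rand_dna(100)
  h <- search_hits(c(q = q), c(s = q))
  expect_gte(nrow(h), 1)
  expect_equal(h$pident[1], 100)
  expect_equal(h$score[1], 100) # 100 * match
  expect_equal(c(h$qstart[1], h$qend[1], h$sstart[1], h$send[1]),
               c(1L, 100L, 1L, 100L))
})

test_that("engine never exceeds and usually equals the exact optimum on seeded pairs", {
  p <- scoring_params()
  set.seed(202)
  agree <- 0L
  n_pairs <- 40L
  for (i in seq_len(n_pairs)) {
    core <- rand_dna(40)
    a <- paste0(rand_dna(80), core, rand_dna(80))
    b <- paste0(rand_dna(80), core, rand_dna(80))
    sw <- smith_waterman(a, b, p)
    h <- search_hits(c(q = a), c(s = b), p)
    best <- if (nrow(h)) max(h$score) else 0L
    expect_lte(best, sw$score)
    if (best == sw$score) agree <- agree + 1L
  }
  expect_gte(agree / n_pairs, 0.95)
})

test_that("a planted diverged segment is found with the expected identity", {
  set.seed(303)
  mitoseq <- rand_dna(16000)
  seg <- substr(mitoseq, 4001, 4500)
  v <- strsplit(seg, "")[[1]]
  pos <- sample(500, 25) # 5% substitutions
  v[pos] <- vapply(v[pos],
                   function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   "")
  planted <- paste(v, collapse = "")
  scaffold <- paste0(rand_dna(50000), planted, rand_dna(49500))
  h <- search_hits(c(mt = mitoseq), c(sc = scaffold))
  h <- filter_hits(h)
  expect_gte(nrow(h), 1)
  top <- h[which.max(h$score), ]
  ov <- min(top$send, 50500) - max(top$sstart, 50001) + 1
  expect_gte(ov / 500, 0.9)
  expect_gte(top$pident, 93)
  expect_lte(top$pident, 97)
})

test_that("both strands are searched and reported consistently", {
  set.seed(404)
  q <- rand_dna(300)
  sub <- paste0(rand_dna(200), revcomp_chr(q), rand_dna(200))
  h <- filter_hits(search_hits(c(q = q), c(s = sub)))
  expect_gte(nrow(h), 1)
  expect_equal(h$strand[1], "-")
  expect_equal(c(h$sstart[1], h$send[1]), c(201L, 500L))
  expect_equal(c(h$qstart[1], h$qend[1]), c(1L, 300L))

  # reverse-complementing the query flips strands and reflects intervals
  h2 <- filter_hits(search_hits(c(q = revcomp_chr(q)), c(s = sub)))
  expect_equal(nrow(h2), nrow(h))
  expect_equal(h2$strand[1], "+")
  expect_equal(c(h2$sstart[1], h2$send[1]), c(h$sstart[1], h$send[1]))
  expect_equal(h2$qstart[1], 300L - h$qend[1] + 1L)
  expect_equal(h2$qend[1], 300L - h$qstart[1] + 1L)
})

test_that("edge inputs give empty results rather than errors", {
  expect_equal(nrow(search_hits(character(0), c(s = "ACGT"))), 0)
  expect_equal(nrow(search_hits(c(q = "ACGTACGTACGT"), c(s = ""))), 0)
  # word size longer than the query: nothing can seed
  expect_equal(nrow(search_hits(c(q = "ACGTAC"), c(s = rand_dna(100)))), 0)
})

test_that("N bases never seed and score as mismatches", {
  set.seed(505)
  q <- rand_dna(100)
  nq <- paste(rep("N", 100), collapse = "")
  expect_equal(nrow(search_hits(c(q = nq), c(s = q))), 0)
  # one N inside an otherwise perfect match lowers identity
  v <- strsplit(q, "")[[1]]
  v[50] <- "N"
  h <- search_hits(c(q = paste(v, collapse = "")), c(s = q))
  expect_gte(nrow(h), 1)
  expect_lt(h$pident[1], 100)
})

test_that("circularize extends and folds coordinates; linear topology refused", {
  s <- "ACGTACGTAA"
  cz <- circularize(s, 4)
  expect_equal(as.character(cz$extended), paste0(s, "ACG"))
  expect_equal(cz$fold(11), 1)
  expect_equal(cz$fold(13), 3)
  # degenerate span: no extension, identity mapping
  cz1 <- circularize(s, 1)
  expect_equal(as.character(cz1$extended), s)
  expect_equal(cz1$fold(7), 7)
  expect_error(circularize(s, 11), "exceeds")
  expect_error(circularize(s, 4, topology = "linear"), "circular")
})

test_that("a NUMT spanning the circular origin is reported folded and flagged", {
  cfg <- sim_config(seed = 21, mito_topology = "circular",
                    n_mito_chromosomes = 1L, mito_lengths = 16389L,
                    itr_length = 0L)
  mito <- generate_mito_genome(cfg)
  L <- mito$total_length
  # construct a junction-spanning copy: last 300 bp + first 300 bp
  mt <- as.character(mito$seq[[1]])
  junction <- paste0(substr(mt, L - 299, L), substr(mt, 1, 300))
  scaffold <- paste0(rand_dna(5000), junction, rand_dna(5000))
  h <- filter_hits(search_hits(mito, c(sc = scaffold)))
  expect_gte(nrow(h), 1)
  top <- h[which.max(h$score), ]
  expect_true(top$wraps_origin)
  expect_gt(top$qstart, top$qend) # folded interval wraps the origin
  # extension may gain a base or two by chance beyond the planted junction
  expect_lte(abs(top$qstart - (L - 299)), 3)
  expect_lte(abs(top$qend - 300), 3)
})

test_that("mitochondrial self-search reports the full-length identity hit first", {
  cfg <- sim_config(seed = 3)
  mito <- generate_mito_genome(cfg)
  h <- search_hits(mito$seq[1], mito$seq[1])
  expect_equal(h$pident[1], 100)
  expect_equal(h$length[1], Biostrings::width(mito$seq)[1])
})
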