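# Duplication families, split pairs, and interruption classification.

fake_numts <- function(mito_start, mito_end, scaffold = "sc1",
                       nuc_start = NULL, strand = "+",
                       mito_chrom = "mt") {
  n <- length(mito_start)
  if (is.null(nuc_start)) nuc_start <- seq(1e4, by = 1e4, length.out = n)
  data.frame(numt_id = sprintf("NUMT_%04d", seq_len(n)),
             nuclear_scaffold = rep_len(scaffold, n),
             nuclear_start = nuc_start,
             nuclear_end = nuc_start + (mito_end - mito_start),
             length = mito_end - mito_start + 1L,
             mito_chromosome = rep_len(mito_chrom, n),
             mito_start = mito_start, mito_end = mito_end,
             strand = rep_len(strand, n), identity = 95,
             evalue = 1e-20, bitscore = 100, wraps_origin = FALSE,
             source_hits = as.character(seq_len(n)),
             stringsAsFactors = FALSE)
}

test_that("duplication grouping applies the reciprocal-overlap rule", {
  # identical origins at two loci: one family of size 2
  d <- group_duplicates(fake_numts(c(100, 100), c(1099, 1099)))
  expect_equal(nrow(d$families), 1L)
  expect_equal(d$families$family_size, 2L)
  expect_equal(d$n_duplicated, 2L)
  expect_equal(d$n_singletons, 0L)

  # 10% overlap is far below the 0.8 default: no family
  d2 <- group_duplicates(fake_numts(c(1, 901), c(1000, 1900)))
  expect_equal(nrow(d2$families), 0L)
  expect_equal(d2$n_singletons, 2L)

  # different mito chromosomes never group
  nm <- fake_numts(c(100, 100), c(1099, 1099))
  nm$mito_chromosome <- c("mt1", "mt2")
  expect_equal(nrow(group_duplicates(nm)$families), 0L)

  # same nuclear locus (self-overlap) does not count as duplication
  n1 <- fake_numts(c(100, 100), c(1099, 1099), nuc_start = c(5000, 5000))
  expect_equal(nrow(group_duplicates(n1)$families), 0L)
})

test_that("family relation matches a brute-force transitive closure", {
  set.seed(77)
  for (rep_i in 1:5) {
    n <- 25
    st <- sample.int(14000, n)
    len <- sample(100:1500, n, replace = TRUE)
    nm <- fake_numts(st, st + len - 1L)
    fam <- group_duplicates(nm, 0.8)
    # brute force: pairwise rule then closure
    M <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      inter <- min(nm$mito_end[i], nm$mito_end[j]) -
        max(nm$mito_start[i], nm$mito_start[j]) + 1
      wi <- nm$mito_end[i] - nm$mito_start[i] + 1
      wj <- nm$mito_end[j] - nm$mito_start[j] + 1
      if (inter > 0 && inter / wi >= 0.8 && inter / wj >= 0.8) {
        M[i, j] <- M[j, i] <- TRUE
      }
    }
    comp <- brute_components(M)
    sizes <- sort(as.integer(table(comp)[table(comp) >= 2]))
    expect_equal(sort(fam$families$family_size), sizes)
  }
})

test_that("raising the overlap threshold never grows family membership", {
  set.seed(88)
  st <- sample.int(10000, 40)
  nm <- fake_numts(st, st + sample(200:800, 40, TRUE))
  prev <- Inf
  for (thr in c(0.5, 0.7, 0.9, 0.99)) {
    d <- group_duplicates(nm, thr)
    memb <- d$n_duplicated
    expect_lte(memb, prev)
    prev <- memb
  }
})

test_that("split pairs require same strand, collinearity, and spacing bounds", {
  # the canonical case: mito [1,500] then [511,900], nuclear gap 3.5 kb
  nm <- fake_numts(c(1, 511), c(500, 900),
                   nuc_start = c(10001, 14001))
  sp <- find_split_pairs(nm)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$gap_start, 10501)
  expect_equal(sp$gap_end, 14000)
  expect_equal(sp$mito_gap, 10L)

  # opposite strands: not reported
  nm2 <- nm; nm2$strand <- c("+", "-")
  expect_equal(nrow(find_split_pairs(nm2)), 0L)

  # anti-collinear on the plus strand (mito order reversed): not reported
  nm3 <- fake_numts(c(511, 1), c(900, 500), nuc_start = c(10001, 14001))
  expect_equal(nrow(find_split_pairs(nm3)), 0L)
  # ... but the same arrangement on the minus strand is collinear
  nm4 <- nm3; nm4$strand <- "-"
  expect_equal(nrow(find_split_pairs(nm4)), 1L)

  # mito gap beyond the bound: not reported
  nm5 <- fake_numts(c(1, 801), c(500, 1200), nuc_start = c(10001, 14001))
  expect_equal(nrow(find_split_pairs(nm5, max_mito_gap = 100L)), 0L)

  # nuclear gap below the separation floor: not reported
  nm6 <- fake_numts(c(1, 511), c(500, 900), nuc_start = c(10001, 10520))
  expect_equal(nrow(find_split_pairs(nm6)), 0L)
})

test_that("windowed trinucleotide entropy behaves as expected", {
  # AT dyad repeat: exactly two trinucleotides, 1 bit in every window
  ent <- trinucleotide_entropy(strrep("AT", 200))
  expect_true(all(abs(ent - 1) < 1e-12))
  # homopolymer: zero entropy
  expect_true(all(trinucleotide_entropy(strrep("A", 200)) == 0))
  # too short to window
  expect_equal(length(trinucleotide_entropy("AC")), 0L)
})

test_that("interruption classification separates repeats, TEs, and plain sequence", {
  set.seed(99)
  # dyad repeat: low complexity
  ic <- classify_interruption(strrep("AT", 200))
  expect_equal(ic$classification, "low_complexity")
  expect_lt(ic$median_entropy, 1.2)

  # a planted library element at 2% divergence: transposable element
  te <- rand_dna(800)
  lib <- Biostrings::DNAStringSet(c(TE_1 = te))
  v <- strsplit(te, "")[[1]]
  pos <- sample(800, 16)
  v[pos] <- vapply(v[pos],
                   function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   "")
  ic2 <- classify_interruption(paste(v, collapse = ""), lib)
  expect_equal(ic2$classification, "transposable_element")
  expect_equal(ic2$evidence, "TE_1")

  # random uniform gaps: overwhelmingly 'other' (Monte-Carlo, fixed seed)
  cls <- vapply(1:200, function(i) {
    classify_interruption(rand_dna(400))$classification
  }, "")
  expect_gte(mean(cls == "other"), 0.99)

  # deterministic given identical input
  g <- rand_dna(500)
  expect_identical(classify_interruption(g)$classification,
                   classify_interruption(g)$classification)
  expect_error(classify_interruption(""), "length")
})

test_that("planted interrupted insertions are recovered as classified split pairs", {
  res <- shared_sim()
  led <- res$genome$ledger
  planted <- led[!is.na(led$interrupted_kind), ]
  expect_equal(nrow(planted), 2L)
  sp <- res$split_pairs
  found <- 0L
  for (i in seq_len(nrow(planted))) {
    ov <- sp$nuclear_scaffold == planted$nuclear_scaffold[i] &
      sp$gap_start <= planted$interruption_end[i] &
      sp$gap_end >= planted$interruption_start[i]
    if (any(ov)) {
      found <- found + 1L
      j <- which(ov)[1]
      inter <- min(sp$gap_end[j], planted$interruption_end[i]) -
        max(sp$gap_start[j], planted$interruption_start[i]) + 1
      elen <- planted$interruption_end[i] - planted$interruption_start[i] + 1
      expect_gte(inter / elen, 0.8)
      expected <- if (planted$interrupted_kind[i] == "te") {
        "transposable_element"
      } else "low_complexity"
      expect_equal(sp$classification[j], expected)
    }
  }
  expect_equal(found, nrow(planted))
})
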