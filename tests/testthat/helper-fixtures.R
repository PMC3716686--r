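# Shared fixtures and independent oracle helpers for the test suite.

rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = p), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# brute-force gene-density scan: count genes intersecting the padded window
# by direct interval comparison (quadratic, independent of GenomicRanges)
brute_density_count <- function(numt_start, numt_end, gene_starts,
                                gene_ends, window_bp = 10000L) {
  half <- window_bp %/% 2L
  ws <- max(1L, numt_start - half)
  we <- numt_end + half
  sum(gene_ends >= ws & gene_starts <= we)
}

# brute-force transitive closure of a pairwise match relation
brute_components <- function(match_matrix) {
  n <- nrow(match_matrix)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (match_matrix[i, j] && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

# recall / precision of NUMT calls against a truth ledger at a reciprocal
# overlap threshold
recovery_metrics <- function(numts, ledger, min_recip = 0.5) {
  ngr <- GenomicRanges::GRanges(
    numts$nuclear_scaffold,
    IRanges::IRanges(numts$nuclear_start, numts$nuclear_end))
  lgr <- GenomicRanges::GRanges(
    ledger$nuclear_scaffold,
    IRanges::IRanges(ledger$nuclear_start, ledger$nuclear_end))
  ov <- GenomicRanges::findOverlaps(ngr, lgr)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(ngr)[qh],
                                          IRanges::ranges(lgr)[sh]))
  ok <- w / IRanges::width(ngr)[qh] >= min_recip &
    w / IRanges::width(lgr)[sh] >= min_recip
  list(recall = length(unique(sh[ok])) / nrow(ledger),
       precision = length(unique(qh[ok])) / nrow(numts))
}

# a small shared pipeline run reused by several test files (computed once)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        seed = 7, nuclear_length = 300000L, n_scaffolds = 2L,
        n_genes = 15L, n_insertions = 20L,
        duplication_spec = list(c(2L, 2L)),
        n_interrupted = 2L, n_intronic = 3L,
        est_spec = c(pure_mito = 3L, chimeric_utr5 = 2L,
                     chimeric_internal = 2L, plain_nuclear = 2L),
        divergence_dist = list(min = 0, max = 0.10, indel_frac = 0.1))
      cache <<- run_pipeline(cfg)
    }
    cache
  }
})
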