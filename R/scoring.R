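# Karlin-Altschul parameterization for the seed-and-extend engine.

.ka_cache <- new.env(parent = emptyenv())

#' Solve for the Karlin-Altschul lambda parameter
#'
#' Finds the unique positive root of the transcendental equation
#' \eqn{\sum_{i,j} p_i p_j e^{\lambda s(i,j)} = 1} for a match/mismatch
#' nucleotide scoring scheme under a given background composition. Local
#' alignment score statistics (E-values) are defined only when the expected
#' per-column score is negative.
#'
#' @param match positive integer match reward.
#' @param mismatch non-positive integer mismatch score.
#' @param background_freqs numeric vector of 4 background nucleotide
#'   frequencies (A, C, G, T); defaults to uniform.
#' @return the positive root `lambda` (nats per score unit); the residual of
#'   the defining equation is below `1e-9`.
#' @examples
#' solve_lambda(1, -1) # log(3) for uniform composition
#' @export
solve_lambda <- function(match, mismatch, background_freqs = rep(0.25, 4)) {
  stopifnot(length(background_freqs) == 4, all(background_freqs > 0))
  p <- background_freqs / sum(background_freqs)
  p2 <- sum(p^2) # probability that two background letters are identical
  if (match <= 0) stop("`match` must be positive")
  escore <- p2 * match + (1 - p2) * mismatch
  if (escore >= 0) {
    stop("expected score is non-negative; local alignment statistics undefined")
  }
  f <- function(l) p2 * exp(l * match) + (1 - p2) * exp(l * mismatch) - 1
  # bracket: f(0) = 0, f'(0) = escore < 0, f -> Inf
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  l <- stats::uniroot(f, c(1e-12, hi), tol = 1e-12)$root
  # Newton polish to drive the residual below 1e-9
  fp <- function(l) {
    p2 * match * exp(l * match) + (1 - p2) * mismatch * exp(l * mismatch)
  }
  for (i in 1:8) {
    r <- f(l)
    if (abs(r) < 1e-12) break
    l <- l - r / fp(l)
  }
  if (abs(f(l)) >= 1e-9) stop("lambda solver failed to converge")
  l
}

#' Estimate the Karlin-Altschul K parameter by Monte-Carlo calibration
#'
#' Simulates pairs of i.i.d. background sequences, records the best ungapped
#' local alignment score of each pair, and inverts the Gumbel mean formula
#' \eqn{E[M] = (\ln(Kmn) + \gamma)/\lambda} for `K`. This is a documented
#' approximation (the lattice-score correction is ignored and the same `K` is
#' reused for gapped scores); pass an explicit `K` to [scoring_params()] to
#' override it.
#'
#' @param match,mismatch scoring scheme.
#' @param background_freqs background composition (length 4, A/C/G/T).
#' @param seq_length,n_sim simulation size; defaults keep calibration under a
#'   couple of seconds.
#' @param seed internal calibration seed (fixed so that identical schemes
#'   always give identical `K`; independent of the user RNG stream).
#' @return scalar `K` estimate.
#' @export
estimate_karlin_k <- function(match, mismatch, background_freqs = rep(0.25, 4),
                              seq_length = 1000L, n_sim = 100L,
                              seed = 904811L) {
  key <- paste(match, mismatch, paste(signif(background_freqs, 6),
                                      collapse = ","), seq_length, n_sim,
               sep = "|")
  if (!is.null(.ka_cache[[key]])) return(.ka_cache[[key]])
  lambda <- solve_lambda(match, mismatch, background_freqs)
  p <- background_freqs / sum(background_freqs)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  best <- integer(n_sim)
  for (i in seq_len(n_sim)) {
    a <- paste(sample(c("A", "C", "G", "T"), seq_length, TRUE, p), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), seq_length, TRUE, p), collapse = "")
    best[i] <- cpp_best_local_ungapped(a, b, match, mismatch)
  }
  gamma <- 0.57721566490153286
  k <- exp(lambda * mean(best) - gamma) / (as.double(seq_length)^2)
  .ka_cache[[key]] <- k
  k
}

#' Scoring parameters for the local-alignment engine
#'
#' Bundles the match/mismatch/affine-gap scheme, the seeding and X-drop
#' extension controls, and the Karlin-Altschul statistics (`lambda`, `K`)
#' used to convert raw scores into bit scores and E-values
#' (\eqn{E = K m n e^{-\lambda S}}). Defaults mirror classic blastn-style
#' parameters: +1/-2 with gap open 5 and gap extend 2, word size 11.
#'
#' @param match,mismatch,gap_open,gap_extend integer scoring scheme; a gap of
#'   length k costs `gap_open + k * gap_extend`.
#' @param word_size exact-match seed length (>= 4).
#' @param xdrop_ungapped,xdrop_gapped X-drop termination thresholds in raw
#'   score units for the ungapped and gapped extension stages.
#' @param lambda,K Karlin-Altschul parameters; computed from the scheme when
#'   `NULL` (`lambda` by root-finding, `K` by [estimate_karlin_k()]).
#' @param background_freqs background composition used for `lambda`/`K`.
#' @param evalue_max,min_hit_length the hit-filtering contract applied by
#'   [filter_hits()]: maximum E-value (default `1e-4`) and minimum nuclear
#'   alignment span in bp (default 50).
#' @param evalue_report loose reporting threshold of the engine itself
#'   (default 10, as in blastn); hits above it are never materialized.
#' @return an object of class `scoring_params`.
#' @export
scoring_params <- function(match = 1L, mismatch = -2L, gap_open = 5L,
                           gap_extend = 2L, word_size = 11L,
                           xdrop_ungapped = 20L, xdrop_gapped = 40L,
                           lambda = NULL, K = NULL,
                           background_freqs = rep(0.25, 4),
                           evalue_max = 1e-4, min_hit_length = 50L,
                           evalue_report = 10) {
  stopifnot(match > 0, mismatch <= 0, gap_open >= 0, gap_extend >= 0,
            word_size >= 4, evalue_max > 0, min_hit_length >= 1)
  if (is.null(lambda)) lambda <- solve_lambda(match, mismatch, background_freqs)
  if (is.null(K)) K <- estimate_karlin_k(match, mismatch, background_freqs)
  stopifnot(lambda > 0, K > 0)
  structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         word_size = as.integer(word_size),
         xdrop_ungapped = as.integer(xdrop_ungapped),
         xdrop_gapped = as.integer(xdrop_gapped),
         lambda = lambda, K = K, background_freqs = background_freqs,
         evalue_max = evalue_max, min_hit_length = as.integer(min_hit_length),
         evalue_report = evalue_report),
    class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat("Local-alignment scoring parameters\n")
  cat(sprintf("  match %+d  mismatch %+d  gap %d/%d  word %d\n",
              x$match, x$mismatch, x$gap_open, x$gap_extend, x$word_size))
  cat(sprintf("  lambda %.6f  K %.4f  E-max %g  min length %d bp\n",
              x$lambda, x$K, x$evalue_max, x$min_hit_length))
  invisible(x)
}

#' E-value of a raw alignment score
#'
#' \eqn{E = K m n e^{-\lambda S}} with `m`, `n` the raw search-space lengths
#' (no edge-effect correction).
#'
#' @param score raw alignment score(s).
#' @param m,n query and subject search-space lengths in bp.
#' @param params a [scoring_params()] object.
#' @return numeric vector of expected chance-hit counts.
#' @export
score_to_evalue <- function(score, m, n, params) {
  params$K * as.double(m) * as.double(n) * exp(-params$lambda * score)
}

#' Bit score of a raw alignment score
#' @inheritParams score_to_evalue
#' @return numeric bit score(s), \eqn{(\lambda S - \ln K)/\ln 2}.
#' @export
score_to_bits <- function(score, params) {
  (params$lambda * score - log(params$K)) / log(2)
}
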