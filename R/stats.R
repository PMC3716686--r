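# Statistical utilities used by the comparative report.

#' Two-sample Student's t-test (equal variance)
#'
#' Classical pooled-variance two-sample t statistic with
#' `df = n_a + n_b - 2` and a two-sided p-value, as used to compare NUMT
#' length distributions between genomes. Degenerate inputs (zero pooled
#' variance) return p = 1 for equal means and p = 0 otherwise, flagged.
#' Welch's unequal-variance form is available behind `var_equal = FALSE`.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @param var_equal pooled-variance Student form when `TRUE` (default).
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, `degenerate`.
#' @export
students_t_test <- function(sample_a, sample_b, var_equal = TRUE) {
  na <- length(sample_a); nb <- length(sample_b)
  if (na < 2 || nb < 2) stop("each sample needs n >= 2")
  ma <- mean(sample_a); mb <- mean(sample_b)
  va <- var(sample_a); vb <- var(sample_b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    df <- na + nb - 2
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (!is.finite(se) || se == 0) {
    return(list(t = if (ma == mb) 0 else sign(ma - mb) * Inf,
                df = df, p = if (ma == mb) 1 else 0,
                mean_a = ma, mean_b = mb, degenerate = TRUE))
  }
  t <- (ma - mb) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df),
       mean_a = ma, mean_b = mb, degenerate = FALSE)
}

#' Pearson correlation on log-log scale
#'
#' Pearson correlation of `log10(x)` vs `log10(y)` with a two-sided p-value
#' from the t transform on `n - 2` degrees of freedom; used to relate
#' genome size to NUMT cumulative percentage across species. Non-positive
#' pairs are excluded (log undefined) and their count reported.
#'
#' @param genome_sizes,cumulative_percents paired positive values.
#' @return list with `r`, `p`, `n`, `n_excluded`.
#' @export
pearson_loglog <- function(genome_sizes, cumulative_percents) {
  stopifnot(length(genome_sizes) == length(cumulative_percents))
  ok <- genome_sizes > 0 & cumulative_percents > 0 &
    is.finite(genome_sizes) & is.finite(cumulative_percents)
  n_excl <- sum(!ok)
  if (n_excl > 0) {
    message(sprintf("pearson_loglog: excluded %d pair(s) with non-positive values",
                    n_excl))
  }
  x <- log10(genome_sizes[ok]); y <- log10(cumulative_percents[ok])
  n <- length(x)
  if (n < 3) stop("insufficient data: fewer than 3 positive pairs")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, n_excluded = n_excl)
}
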