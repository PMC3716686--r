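# Turn filtered alignment hits into NUMT calls and genome-level summaries.

#' Filter alignment hits by E-value and length
#'
#' Applies the hit-filtering contract used throughout the pipeline: retain
#' hits with `evalue <= evalue_max` (maximum expectation value, inclusive)
#' and a nuclear alignment span of at least `min_hit_length` bp (hits
#' shorter than the threshold are ignored; the boundary value is retained).
#' Input order is preserved.
#'
#' @param hits a hit `data.frame` from [search_hits()].
#' @param evalue_max maximum E-value (default `1e-4`).
#' @param min_hit_length minimum nuclear span in bp (default 50).
#' @return the retained rows, in stable input order.
#' @export
filter_hits <- function(hits, evalue_max = 1e-4, min_hit_length = 50L) {
  if (nrow(hits) == 0) return(hits)
  span <- abs(hits$send - hits$sstart) + 1L
  hits[hits$evalue <= evalue_max & span >= min_hit_length, , drop = FALSE]
}

#' Call NUMTs from filtered alignment hits
#'
#' In `per_hit` mode (the default) every hit becomes one NUMT, mirroring
#' per-alignment reporting. In `merged` mode hits whose nuclear intervals
#' overlap on the same scaffold are unioned into a single NUMT that keeps
#' the best E-value/score among its source hits and lists all of them.
#' Identifiers are deterministic (scaffold, then start order).
#'
#' @param hits filtered hits (see [filter_hits()]).
#' @param mode `"per_hit"` or `"merged"`.
#' @return a `data.frame` of NUMT calls: `numt_id`, `nuclear_scaffold`,
#'   `nuclear_start`, `nuclear_end`, `length` (nuclear span),
#'   `mito_chromosome`, `mito_start`, `mito_end`, `strand`, `identity`,
#'   `evalue`, `bitscore`, `wraps_origin`, `source_hits` (comma-separated
#'   row indices into `hits`).
#' @export
call_numts <- function(hits, mode = c("per_hit", "merged")) {
  mode <- match.arg(mode)
  cols <- c("numt_id", "nuclear_scaffold", "nuclear_start", "nuclear_end",
            "length", "mito_chromosome", "mito_start", "mito_end", "strand",
            "identity", "evalue", "bitscore", "wraps_origin", "source_hits")
  if (nrow(hits) == 0) {
    out <- data.frame(numt_id = character(), nuclear_scaffold = character(),
                      nuclear_start = integer(), nuclear_end = integer(),
                      length = integer(), mito_chromosome = character(),
                      mito_start = integer(), mito_end = integer(),
                      strand = character(), identity = numeric(),
                      evalue = numeric(), bitscore = numeric(),
                      wraps_origin = logical(), source_hits = character(),
                      stringsAsFactors = FALSE)
    return(out[, cols])
  }
  base <- data.frame(
    nuclear_scaffold = hits$sseqid,
    nuclear_start = pmin(hits$sstart, hits$send),
    nuclear_end = pmax(hits$sstart, hits$send),
    mito_chromosome = hits$qseqid,
    mito_start = hits$qstart, mito_end = hits$qend,
    strand = hits$strand, identity = hits$pident,
    evalue = hits$evalue, bitscore = hits$bitscore,
    wraps_origin = if ("wraps_origin" %in% names(hits)) hits$wraps_origin
                   else FALSE,
    source_hits = as.character(seq_len(nrow(hits))),
    stringsAsFactors = FALSE)
  base$length <- base$nuclear_end - base$nuclear_start + 1L

  if (mode == "merged") {
    gr <- GenomicRanges::GRanges(base$nuclear_scaffold,
                                 IRanges::IRanges(base$nuclear_start,
                                                  base$nuclear_end))
    red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
    ov <- GenomicRanges::findOverlaps(gr, red)
    grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    merged <- lapply(split(seq_len(nrow(base)), grp), function(ix) {
      b <- base[ix, , drop = FALSE]
      best <- ix[which.min(b$evalue)]
      bm <- b[b$mito_chromosome == base$mito_chromosome[best], , drop = FALSE]
      data.frame(
        nuclear_scaffold = b$nuclear_scaffold[1],
        nuclear_start = min(b$nuclear_start),
        nuclear_end = max(b$nuclear_end),
        mito_chromosome = base$mito_chromosome[best],
        mito_start = min(bm$mito_start), mito_end = max(bm$mito_end),
        strand = base$strand[best],
        identity = base$identity[best],
        evalue = min(b$evalue), bitscore = max(b$bitscore),
        wraps_origin = any(b$wraps_origin),
        source_hits = paste(ix, collapse = ","),
        stringsAsFactors = FALSE)
    })
    base <- do.call(rbind, merged)
    base$length <- base$nuclear_end - base$nuclear_start + 1L
  }
  base <- base[order(base$nuclear_scaffold, base$nuclear_start,
                     base$nuclear_end), , drop = FALSE]
  base$numt_id <- sprintf("NUMT_%04d", seq_len(nrow(base)))
  rownames(base) <- NULL
  base[, cols]
}

# union of mito-origin intervals in bp, handling origin-wrapping intervals
.mito_union_bp <- function(numts, mito_widths) {
  if (nrow(numts) == 0) return(0)
  rows <- list()
  for (i in seq_len(nrow(numts))) {
    L <- mito_widths[[numts$mito_chromosome[i]]]
    s <- numts$mito_start[i]; e <- numts$mito_end[i]
    if (isTRUE(numts$wraps_origin[i]) || e < s) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = numts$mito_chromosome[i],
        start = c(s, 1L), end = c(L, e))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = numts$mito_chromosome[i], start = s, end = pmin(e, L))
    }
  }
  d <- do.call(rbind, rows)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(d$start, d$end)))
  sum(as.double(GenomicRanges::width(gr)))
}

#' Genome-level NUMT summary statistics
#'
#' Computes the per-genome statistics used to compare NUMT content across
#' species: count, total bp (sum of NUMT lengths; the cumulative-percentage
#' convention), union bp (overlaps collapsed, reported alongside),
#' cumulative percentage of the nuclear genome, fraction of the
#' mitochondrial genome covered by the union of NUMT origins, the ratio of
#' total NUMT bp to mtDNA length, and length-distribution moments (the
#' variance is reported with both the population `n` and sample `n-1`
#' denominators).
#'
#' @param numts NUMT calls from [call_numts()].
#' @param genome_size nuclear genome size in bp (sum of scaffold lengths).
#' @param mito a [MitoGenome] (or named vector of chromosome lengths).
#' @return object of class `NumtSummary` (a list of named statistics).
#' @export
summarize_numts <- function(numts, genome_size, mito) {
  stopifnot(genome_size > 0)
  widths <- if (is(mito, "MitoGenome")) {
    setNames(Biostrings::width(mito$seq), names(mito$seq))
  } else mito
  mito_total <- sum(as.double(widths))
  n <- nrow(numts)
  if (n == 0) {
    out <- list(n_numts = 0L, total_bp = 0, union_bp = 0,
                genome_size = genome_size, cumulative_percent = 0,
                cumulative_percent_union = 0, mt_fraction_transferred = 0,
                mean_length = NA_real_, median_length = NA_real_,
                length_variance = NA_real_, length_variance_sample = NA_real_,
                min_length = NA_real_, max_length = NA_real_,
                identity_range = c(NA_real_, NA_real_),
                identity_defined = FALSE,
                ratio_to_mtdna = 0, mito_total = mito_total)
    class(out) <- "NumtSummary"
    return(out)
  }
  len <- as.double(numts$length)
  total_bp <- sum(len)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    numts$nuclear_scaffold,
    IRanges::IRanges(numts$nuclear_start, numts$nuclear_end)))
  union_bp <- sum(as.double(GenomicRanges::width(gr)))
  mt_cov <- .mito_union_bp(numts, widths)
  out <- list(
    n_numts = n,
    total_bp = total_bp,
    union_bp = union_bp,
    genome_size = genome_size,
    cumulative_percent = 100 * total_bp / genome_size,
    cumulative_percent_union = 100 * union_bp / genome_size,
    mt_fraction_transferred = 100 * mt_cov / mito_total,
    mean_length = mean(len),
    median_length = median(len),
    length_variance = mean((len - mean(len))^2), # population denominator n
    length_variance_sample = if (n > 1) var(len) else NA_real_,
    min_length = min(len), max_length = max(len),
    identity_range = range(numts$identity),
    identity_defined = TRUE,
    ratio_to_mtdna = total_bp / mito_total,
    mito_total = mito_total)
  class(out) <- "NumtSummary"
  out
}

#' @export
print.NumtSummary <- function(x, ...) {
  cat("NUMT summary\n")
  cat(sprintf("  NUMTs: %d  total %.0f bp (union %.0f bp)\n",
              x$n_numts, x$total_bp, x$union_bp))
  cat(sprintf("  cumulative %% of genome: %.4f%% (union %.4f%%)\n",
              x$cumulative_percent, x$cumulative_percent_union))
  cat(sprintf("  mtDNA fraction transferred: %.2f%%  ratio to mtDNA: %.2f\n",
              x$mt_fraction_transferred, x$ratio_to_mtdna))
  if (x$n_numts > 0) {
    cat(sprintf("  length: mean %.0f  median %.0f  range [%.0f, %.0f]  variance %.0f\n",
                x$mean_length, x$median_length, x$min_length, x$max_length,
                x$length_variance))
    cat(sprintf("  identity: %.2f-%.2f%%\n", x$identity_range[1],
                x$identity_range[2]))
  }
  invisible(x)
}
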