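# Duplication families, split NUMT pairs, and interruption classification.

#' Group NUMTs into post-insertion duplication families
#'
#' Two NUMTs are treated as copies of the same original insertion when they
#' originate from the same location in the mitochondrial genome: their
#' mitochondrial intervals reciprocally overlap by at least
#' `min_reciprocal_overlap` on the same mitochondrial chromosome while
#' their nuclear loci are distinct. Families are the connected components
#' of this relation (transitive closure); singletons are counted but
#' excluded from the duplication report.
#'
#' @param numts NUMT calls from [call_numts()].
#' @param min_reciprocal_overlap required reciprocal overlap fraction of the
#'   mitochondrial origin intervals (default 0.8).
#' @return list with `families` (`data.frame`: family_id, members
#'   (comma-separated numt ids), family_size, mito_chromosome,
#'   rep_mito_start, rep_mito_end), `n_duplicated` (NUMTs in families of
#'   size >= 2), and `n_singletons`.
#' @export
group_duplicates <- function(numts, min_reciprocal_overlap = 0.8) {
  n <- nrow(numts)
  empty <- data.frame(family_id = character(), members = character(),
                      family_size = integer(), mito_chromosome = character(),
                      rep_mito_start = integer(), rep_mito_end = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0) {
    return(list(families = empty, n_duplicated = 0L, n_singletons = 0L))
  }
  gr <- GenomicRanges::GRanges(numts$mito_chromosome,
                               IRanges::IRanges(numts$mito_start,
                                                numts$mito_end))
  ov <- GenomicRanges::findOverlaps(gr, gr)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  keep <- qi < si
  qi <- qi[keep]; si <- si[keep]
  if (length(qi)) {
    inter <- pmin(numts$mito_end[qi], numts$mito_end[si]) -
      pmax(numts$mito_start[qi], numts$mito_start[si]) + 1L
    wq <- numts$mito_end[qi] - numts$mito_start[qi] + 1L
    ws <- numts$mito_end[si] - numts$mito_start[si] + 1L
    recip <- inter / wq >= min_reciprocal_overlap &
      inter / ws >= min_reciprocal_overlap
    distinct <- !(numts$nuclear_scaffold[qi] == numts$nuclear_scaffold[si] &
                    numts$nuclear_start[qi] == numts$nuclear_start[si] &
                    numts$nuclear_end[qi] == numts$nuclear_end[si])
    qi <- qi[recip & distinct]; si <- si[recip & distinct]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = qi, to = si), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  fam_comp <- as.integer(names(sizes)[sizes >= 2])
  fams <- lapply(seq_along(fam_comp), function(k) {
    ix <- which(comp == fam_comp[k])
    rep_i <- ix[which.max(numts$mito_end[ix] - numts$mito_start[ix])]
    data.frame(family_id = sprintf("FAM_%03d", k),
               members = paste(numts$numt_id[ix], collapse = ","),
               family_size = length(ix),
               mito_chromosome = numts$mito_chromosome[rep_i],
               rep_mito_start = numts$mito_start[rep_i],
               rep_mito_end = numts$mito_end[rep_i],
               stringsAsFactors = FALSE)
  })
  families <- if (length(fams)) do.call(rbind, fams) else empty
  # deterministic order: by chromosome then representative start
  if (nrow(families)) {
    families <- families[order(families$mito_chromosome,
                               families$rep_mito_start), , drop = FALSE]
    families$family_id <- sprintf("FAM_%03d", seq_len(nrow(families)))
    rownames(families) <- NULL
  }
  list(families = families,
       n_duplicated = sum(families$family_size),
       n_singletons = n - sum(families$family_size))
}

#' Find split NUMT pairs (neighbouring mitochondrial origin, distant nuclear loci)
#'
#' Reports pairs of NUMTs on the same scaffold and strand whose
#' mitochondrial origins are closely spaced and collinear (gap between the
#' origin intervals at most `max_mito_gap`) but whose nuclear intervals are
#' separated by at least `min_nuclear_separation`, i.e. candidates for a
#' single insertion later interrupted by an interposed element. The nuclear
#' gap interval is reported for extraction and classification.
#'
#' @param numts NUMT calls from [call_numts()].
#' @param max_mito_gap maximum gap between the mitochondrial origin
#'   intervals in bp (default 100); small negative gaps down to
#'   `min_mito_gap` tolerate end erosion of the alignments.
#' @param min_nuclear_separation minimum nuclear gap in bp (default 50).
#' @param max_nuclear_separation extraction cap in bp (default 50,000).
#' @param min_mito_gap most negative allowed origin gap (default -20).
#' @return `data.frame`: numt_id_a, numt_id_b, nuclear_scaffold, gap_start,
#'   gap_end, nuclear_gap, mito_gap, strand.
#' @export
find_split_pairs <- function(numts, max_mito_gap = 100L,
                             min_nuclear_separation = 50L,
                             max_nuclear_separation = 50000L,
                             min_mito_gap = -20L) {
  out <- data.frame(numt_id_a = character(), numt_id_b = character(),
                    nuclear_scaffold = character(), gap_start = integer(),
                    gap_end = integer(), nuclear_gap = integer(),
                    mito_gap = integer(), strand = character(),
                    stringsAsFactors = FALSE)
  if (nrow(numts) < 2) return(out)
  ord <- order(numts$nuclear_scaffold, numts$nuclear_start)
  nu <- numts[ord, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(nu) - 1L)) {
    for (j in (i + 1L):nrow(nu)) {
      if (nu$nuclear_scaffold[j] != nu$nuclear_scaffold[i]) break
      if (nu$strand[j] != nu$strand[i]) next
      if (nu$mito_chromosome[j] != nu$mito_chromosome[i]) next
      ngap <- nu$nuclear_start[j] - nu$nuclear_end[i] - 1L
      if (ngap < min_nuclear_separation) next
      if (ngap > max_nuclear_separation) break
      # collinearity: on + strand the downstream nuclear copy continues the
      # mito coordinate; on - strand it precedes it
      if (nu$strand[i] == "+") {
        mgap <- nu$mito_start[j] - nu$mito_end[i] - 1L
      } else {
        mgap <- nu$mito_start[i] - nu$mito_end[j] - 1L
      }
      if (mgap < min_mito_gap || mgap > max_mito_gap) next
      rows[[length(rows) + 1L]] <- data.frame(
        numt_id_a = nu$numt_id[i], numt_id_b = nu$numt_id[j],
        nuclear_scaffold = nu$nuclear_scaffold[i],
        gap_start = nu$nuclear_end[i] + 1L,
        gap_end = nu$nuclear_start[j] - 1L,
        nuclear_gap = ngap, mito_gap = mgap, strand = nu$strand[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Windowed trinucleotide entropy of a sequence
#'
#' Shannon entropy (bits) of overlapping trinucleotides in sliding windows.
#'
#' @param seq character/`DNAString` sequence.
#' @param window,step window size and step in bp (defaults 64/32).
#' @return numeric vector of per-window entropies (window start positions as
#'   names); length 0 for sequences shorter than 3 bp.
#' @export
trinucleotide_entropy <- function(seq, window = 64L, step = 32L) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n < 3) return(numeric(0))
  starts <- seq(1L, max(1L, n - 2L), by = step)
  starts <- starts[starts + 2L <= n | starts == 1L]
  ent <- vapply(starts, function(st) {
    en <- min(st + window - 1L, n)
    sub <- substr(s, st, en)
    l <- nchar(sub)
    if (l < 3) return(0)
    tri <- substring(sub, 1:(l - 2), 3:l)
    p <- table(tri) / length(tri)
    -sum(p * log2(p))
  }, 0)
  names(ent) <- starts
  ent
}

#' Classify the sequence interposed between a split NUMT pair
#'
#' Computes a windowed low-complexity score (Shannon entropy of
#' trinucleotides, window 64 bp, step 32 bp) and, when a repeat library is
#' supplied, aligns the gap sequence against it with the search engine.
#' Precedence: `transposable_element` if a library alignment passes the hit
#' filter (E <= `evalue_max`, >= `min_hit_length` bp), else
#' `low_complexity` if at least half of the windows fall below the entropy
#' threshold, else `other`.
#'
#' @param gap_seq the extracted nuclear gap sequence (character or
#'   `DNAString`), length >= 1.
#' @param repeat_library optional `DNAStringSet` of repeat/TE sequences.
#' @param entropy_threshold bits; windows below it count as low-complexity
#'   (default 1.2).
#' @param low_complexity_fraction fraction of windows that must be below
#'   threshold (default 0.5).
#' @param params [scoring_params()] used for the library search.
#' @return object of class `InterruptionCall`: list with `classification`
#'   (`low_complexity` / `transposable_element` / `other`), `evidence`
#'   (repeat hit id or entropy summary), `median_entropy`,
#'   `frac_low_windows`, `library_hit`.
#' @export
classify_interruption <- function(gap_seq, repeat_library = NULL,
                                  entropy_threshold = 1.2,
                                  low_complexity_fraction = 0.5,
                                  params = scoring_params()) {
  s <- toupper(as.character(gap_seq))
  if (nchar(s) < 1) stop("gap sequence must have length >= 1")
  ent <- trinucleotide_entropy(s)
  frac_low <- if (length(ent)) mean(ent < entropy_threshold) else 0
  lib_hit <- NULL
  if (!is.null(repeat_library) && length(repeat_library) > 0) {
    h <- search_hits(repeat_library, Biostrings::DNAStringSet(c(gap = s)),
                     params = params)
    h <- filter_hits(h, params$evalue_max, params$min_hit_length)
    if (nrow(h) > 0) lib_hit <- h[1, , drop = FALSE]
  } else if (!is.null(repeat_library)) {
    message("empty repeat library; classifying by low-complexity only")
  }
  cls <- if (!is.null(lib_hit)) "transposable_element" else {
    if (length(ent) && frac_low >= low_complexity_fraction) "low_complexity"
    else "other"
  }
  structure(list(
    classification = cls,
    evidence = if (!is.null(lib_hit)) lib_hit$qseqid else {
      sprintf("%.0f%% of windows below %.2f bits", 100 * frac_low,
              entropy_threshold)
    },
    median_entropy = if (length(ent)) median(ent) else NA_real_,
    frac_low_windows = frac_low,
    library_hit = lib_hit), class = "InterruptionCall")
}

#' @export
print.InterruptionCall <- function(x, ...) {
  cat(sprintf("InterruptionCall: %s (%s)\n", x$classification, x$evidence))
  invisible(x)
}

#' Extract and classify the gaps of split NUMT pairs
#'
#' Convenience wrapper: extracts each [find_split_pairs()] gap from the
#' genome and runs [classify_interruption()].
#'
#' @param pairs output of [find_split_pairs()].
#' @param genome nuclear `DNAStringSet` (or [synthetic_genome]).
#' @param repeat_library optional `DNAStringSet`.
#' @param ... passed to [classify_interruption()].
#' @return `pairs` with added `classification` and `evidence` columns.
#' @export
classify_split_pairs <- function(pairs, genome, repeat_library = NULL, ...) {
  if (is(genome, "synthetic_genome")) genome <- genome$nuclear
  if (nrow(pairs) == 0) {
    pairs$classification <- character(0)
    pairs$evidence <- character(0)
    return(pairs)
  }
  cls <- character(nrow(pairs)); evd <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sc <- genome[[pairs$nuclear_scaffold[i]]]
    if (pairs$gap_end[i] > length(sc) || pairs$gap_start[i] < 1) {
      stop("consistency error: gap extraction beyond scaffold bounds")
    }
    gseq <- as.character(Biostrings::subseq(sc, pairs$gap_start[i],
                                            pairs$gap_end[i]))
    ic <- classify_interruption(gseq, repeat_library, ...)
    cls[i] <- ic$classification
    evd[i] <- as.character(ic$evidence)[1]
  }
  pairs$classification <- cls
  pairs$evidence <- evd
  pairs
}
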