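# Seed-and-extend nucleotide local alignment with Karlin-Altschul E-values.

# Coerce character / DNAString / DNAStringSet input to a named DNAStringSet.
.as_dna_set <- function(x, default_name = "seq") {
  if (is(x, "DNAStringSet")) {
    if (is.null(names(x))) names(x) <- paste0(default_name, seq_along(x))
    return(x)
  }
  if (is(x, "DNAString")) x <- as.character(x)
  if (is.character(x)) {
    s <- Biostrings::DNAStringSet(x)
    if (length(s) > 0) {
      names(s) <- if (!is.null(names(x))) names(x) else {
        if (length(s) == 1) default_name else {
          paste0(default_name, seq_along(s))
        }
      }
    }
    return(s)
  }
  stop("cannot interpret input as DNA sequence(s)")
}

.empty_hits <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             strand = character(), score = integer(), gaps = integer(),
             wraps_origin = logical(), stringsAsFactors = FALSE)
}

#' Search a nucleotide query against a subject genome
#'
#' In-house BLASTN-like search: exact `word_size`-mer seeding (one-hit),
#' ungapped X-drop extension, gapped affine X-drop extension, and
#' Karlin-Altschul E-values. Both strands are searched by reverse
#' complementing the query; subject coordinates are always reported on the
#' plus strand and query intervals are orientation-normalized (ascending),
#' with a `strand` column. `N` never seeds and scores as a mismatch.
#'
#' For a circular query topology each query chromosome is extended by a
#' prefix copy (see [circularize()]) so that alignments can cross the
#' origin; reported query intervals are folded back to `[1, L]`, hits
#' crossing the origin carry `wraps_origin = TRUE` (their `qend` is the
#' folded, numerically smaller coordinate), and cyclic duplicates of
#' already-reported hits are removed.
#'
#' @param query query sequence(s): a [MitoGenome], `DNAStringSet`, or named
#'   character vector. Typically the mitochondrial genome.
#' @param subject subject sequence(s): `DNAStringSet` or named character
#'   vector; typically the nuclear scaffolds.
#' @param params a [scoring_params()] object.
#' @param topology `"linear"` or `"circular"`; taken from the query when it
#'   is a [MitoGenome].
#' @param max_hit_span maximum alignment span allowed to cross a circular
#'   origin (defaults to the full chromosome length).
#' @return a `data.frame` of alignment hits with BLAST outfmt-6-compatible
#'   columns (`qseqid sseqid pident length mismatch gapopen qstart qend
#'   sstart send evalue bitscore`) plus `strand`, raw `score`, `gaps`, and
#'   `wraps_origin`; 1-based closed coordinates, sorted by decreasing score.
#' @seealso [filter_hits()], [smith_waterman()], [write_hits_tsv()]
#' @export
search_hits <- function(query, subject, params = scoring_params(),
                        topology = NULL, max_hit_span = NULL) {
  if (is(query, "MitoGenome")) {
    if (is.null(topology)) topology <- query$topology
    query <- query$seq
  }
  if (is.null(topology)) topology <- "linear"
  topology <- match.arg(topology, c("linear", "circular"))
  qset <- .as_dna_set(query, "query")
  sset <- .as_dna_set(subject, "subject")
  if (length(qset) == 0 || length(sset) == 0) return(.empty_hits())

  n_space <- sum(as.double(Biostrings::width(sset)))
  out <- list()
  for (qi in seq_along(qset)) {
    qname <- names(qset)[qi]
    L <- Biostrings::width(qset)[qi]
    if (L == 0) next
    if (topology == "circular") {
      span <- if (is.null(max_hit_span)) L else max_hit_span
      circ <- circularize(qset[[qi]], span)
      qseq <- as.character(circ$extended)
    } else {
      qseq <- as.character(qset[[qi]])
    }
    qrc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(qseq)))
    Lext <- nchar(qseq)
    for (si in seq_along(sset)) {
      sname <- names(sset)[si]
      sseq <- as.character(sset[[si]])
      if (nchar(sseq) == 0) next
      # reporting floor: raw score at the loose reporting E-value, so junk
      # seed extensions are not materialized (the strict 1e-4 filter is
      # applied later by filter_hits)
      ereport <- if (is.null(params$evalue_report)) 10 else params$evalue_report
      min_report <- max(1, ceiling(
        log(params$K * as.double(L) * n_space / ereport) / params$lambda))
      min_ungapped <- max(params$word_size * params$match, min_report - 10L)
      for (strand in c("+", "-")) {
        qs <- if (strand == "+") qseq else qrc
        h <- cpp_seed_extend(qs, sseq, params$match, params$mismatch,
                             params$gap_open, params$gap_extend,
                             params$word_size, params$xdrop_ungapped,
                             params$xdrop_gapped, min_ungapped, min_report)
        if (nrow(h) == 0) next
        if (strand == "-") {
          tmp <- h$qstart
          h$qstart <- Lext - h$qend + 1L
          h$qend <- Lext - tmp + 1L
        }
        h$qseqid <- qname
        h$sseqid <- sname
        h$strand <- strand
        out[[length(out) + 1L]] <-
          .fold_circular(h, L, Lext, topology == "circular")
      }
    }
  }
  if (length(out) == 0) return(.empty_hits())
  hits <- do.call(rbind, out)
  # attach statistics; m = original query chromosome length
  qlen <- setNames(Biostrings::width(qset), names(qset))
  hits$evalue <- score_to_evalue(hits$score, qlen[hits$qseqid], n_space, params)
  hits$bitscore <- round(score_to_bits(hits$score, params), 1)
  hits$pident <- round(100 * hits$nident / hits$length, 2)
  hits <- hits[order(-hits$score, hits$sseqid, hits$sstart, hits$qstart), ]
  rownames(hits) <- NULL
  hits[, c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
           "qstart", "qend", "sstart", "send", "evalue", "bitscore",
           "strand", "score", "gaps", "wraps_origin")]
}

# Fold hit coordinates of a circularized query back into [1, L] and drop
# cyclic duplicates (a hit lying wholly in the extension whose folded image
# equals an already-kept hit).
.fold_circular <- function(h, L, Lext, circular) {
  if (!circular) {
    h$wraps_origin <- FALSE
    return(h)
  }
  fold <- function(p) ((p - 1L) %% L) + 1L
  h$wraps_origin <- h$qstart <= L & h$qend > L
  dup_key <- paste(fold(h$qstart), fold(h$qend), h$sstart, h$send, h$strand)
  keep <- !duplicated(dup_key)
  h <- h[keep, , drop = FALSE]
  h$qstart <- fold(h$qstart)
  h$qend <- fold(h$qend)
  h
}

#' Extend a circular sequence so alignments can cross the origin
#'
#' Appends the first `max_hit_span - 1` bases of a circular molecule to its
#' end and returns the extended sequence together with the coordinate
#' mapping rule (positions fold modulo the original length).
#'
#' @param seq a `DNAString`/character circular sequence.
#' @param max_hit_span maximum alignment span that must fit across the
#'   origin; must not exceed the sequence length.
#' @param topology declared topology; anything but `"circular"` is refused.
#' @return list with `extended` (`DNAString`), `original_length`, and
#'   `fold(pos)`, a function mapping extended to original coordinates.
#' @export
circularize <- function(seq, max_hit_span, topology = "circular") {
  if (!identical(topology, "circular")) {
    stop("circularize() applies only to circular topology")
  }
  s <- if (is(seq, "DNAString")) seq else Biostrings::DNAString(as.character(seq))
  L <- length(s)
  if (max_hit_span > L) stop("max_hit_span exceeds sequence length")
  ext <- if (max_hit_span >= 2) {
    Biostrings::xscat(s, Biostrings::subseq(s, 1L, max_hit_span - 1L))
  } else s
  list(extended = ext, original_length = L,
       fold = function(pos) ((pos - 1L) %% L) + 1L)
}

#' Exact Smith-Waterman local alignment (test oracle)
#'
#' Full-matrix affine-gap local alignment (Gotoh recurrences) computed in R
#' with row-vectorized dynamic programming, independent of the
#' seed-and-extend engine. Used as the exact oracle in the test suite.
#' Tie-breaking during traceback is deterministic: match > substitution >
#' gap-in-`a` > gap-in-`b`, and among equal-score cells the one with the
#' smallest `a` then `b` end-coordinate is chosen.
#'
#' @param a,b character (or `DNAString`) sequences; `|a| * |b|` must not
#'   exceed `1e7` cells.
#' @param params a [scoring_params()] object (only the scoring scheme is
#'   used).
#' @return list with `score`, end coordinates `a_end`/`b_end`, start
#'   coordinates `a_start`/`b_start`, and the aligned strings
#'   `alignment = c(a', b')` with `-` for gaps (empty for score 0).
#' @export
smith_waterman <- function(a, b, params = scoring_params()) {
  av <- strsplit(toupper(as.character(a)), "")[[1]]
  bv <- strsplit(toupper(as.character(b)), "")[[1]]
  m <- length(av); n <- length(bv)
  if (as.double(m) * n > 1e7) {
    stop("instance too large for the exact oracle (> 1e7 cells)")
  }
  if (m == 0 || n == 0) {
    return(list(score = 0, a_start = NA, a_end = NA, b_start = NA, b_end = NA,
                alignment = c("", "")))
  }
  mt <- params$match; ms <- params$mismatch
  go <- params$gap_open; ge <- params$gap_extend
  H <- matrix(0, m + 1, n + 1)
  Fv <- rep(-Inf, n + 1) # vertical gap state (consumes a), per column
  js <- seq_len(n)
  for (i in seq_len(m)) {
    sub <- ifelse(av[i] == bv & av[i] %in% c("A", "C", "G", "T"), mt, ms)
    diagv <- H[i, js] + sub
    Fv <- pmax(H[i, ] - go - ge, Fv - ge)
    hnh <- pmax(0, diagv, Fv[js + 1L]) # all sources except horizontal
    # horizontal gap (consumes b): last run starts at a non-horizontal cell
    cm <- cummax(c(-Inf, hnh[-n] + js[-n] * ge))
    E <- cm - go - js * ge
    H[i + 1L, js + 1L] <- pmax(hnh, E)
  }
  best <- max(H)
  if (best <= 0) {
    return(list(score = 0, a_start = NA, a_end = NA, b_start = NA, b_end = NA,
                alignment = c("", "")))
  }
  # deterministic argmax: smallest a-end, then smallest b-end
  idx <- which(H == best)
  ii <- (idx - 1L) %% (m + 1L) + 1L
  jj <- (idx - 1L) %/% (m + 1L) + 1L
  o <- order(ii, jj)[1L]
  i <- ii[o]; j <- jj[o]
  a_end <- i - 1L; b_end <- j - 1L
  # traceback by recomputation with the documented preference order
  pa <- character(0); pb <- character(0)
  v <- H[i, j]
  while (v > 0) {
    moved <- FALSE
    if (i > 1 && j > 1) {
      is_match <- av[i - 1L] == bv[j - 1L] && av[i - 1L] %in% c("A", "C", "G", "T")
      sc <- if (is_match) mt else ms
      if (H[i - 1L, j - 1L] + sc == v) {
        pa <- c(av[i - 1L], pa); pb <- c(bv[j - 1L], pb)
        i <- i - 1L; j <- j - 1L; v <- H[i, j]; moved <- TRUE
      }
    }
    if (!moved && j > 1) { # gap in a: consume b
      for (k in seq_len(j - 1L)) {
        if (H[i, j - k] - go - k * ge == v) {
          pa <- c(rep("-", k), pa); pb <- c(bv[(j - k):(j - 1L)], pb)
          j <- j - k; v <- H[i, j]; moved <- TRUE
          break
        }
      }
    }
    if (!moved && i > 1) { # gap in b: consume a
      for (k in seq_len(i - 1L)) {
        if (H[i - k, j] - go - k * ge == v) {
          pa <- c(av[(i - k):(i - 1L)], pa); pb <- c(rep("-", k), pb)
          i <- i - k; v <- H[i, j]; moved <- TRUE
          break
        }
      }
    }
    if (!moved) break # zero-floor restart cell
  }
  list(score = best, a_start = i, a_end = a_end, b_start = j, b_end = b_end,
       alignment = c(paste(pa, collapse = ""), paste(pb, collapse = "")))
}
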