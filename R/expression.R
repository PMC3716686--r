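# Expressed-NUMT detection from EST sets: contaminant filtering, chimera
# detection, genomic placement, and stop-codon screening under universal and
# mitochondrial genetic codes.

# per-EST mitochondrial alignment blocks (on the EST's own coordinates)
.est_mito_blocks <- function(est_name, est_seq, mito, params) {
  h <- search_hits(Biostrings::DNAStringSet(setNames(est_seq, est_name)),
                   mito$seq, params = params)
  # query = EST here; mito chromosomes are the subjects
  h
}

#' Screen ESTs for mitochondrial content
#'
#' Partitions an EST set into pure mitochondrial transcripts (contaminants
#' to remove), chimeric candidates (an aligned mitochondrial block passing
#' the hit filter joined to at least `min_flank` bp of contiguous
#' non-mitochondrial sequence: evidence of an expressed NUMT), and ESTs
#' without mitochondrial homology. An EST is pure mitochondrial when its
#' mitochondrial alignments cover at least `pure_coverage` of its length at
#' `pure_identity` percent identity or better.
#'
#' @param ests `DNAStringSet` (or named character) of EST sequences.
#' @param mito a [MitoGenome].
#' @param params [scoring_params()]; the hit filter uses
#'   `params$evalue_max` and `params$min_hit_length`.
#' @param pure_coverage coverage fraction for the pure-mito call
#'   (default 0.95).
#' @param pure_identity minimum identity percent for the pure-mito call
#'   (default 98).
#' @param min_flank minimum contiguous non-mitochondrial block in bp
#'   (default 50).
#' @return list with `pure_mito`, `chimeric`, `no_mt` (character vectors of
#'   EST ids) and `blocks`: per-EST `data.frame` of mitochondrial blocks
#'   (est_id, est_start, est_end, mito_chromosome, mito_start, mito_end,
#'   strand, identity, evalue) for the chimeric candidates.
#' @export
screen_ests <- function(ests, mito, params = scoring_params(),
                        pure_coverage = 0.95, pure_identity = 98,
                        min_flank = 50L) {
  eset <- .as_dna_set(ests, "est")
  pure <- character(0); chim <- character(0); nomt <- character(0)
  blocks <- list()
  for (i in seq_along(eset)) {
    id <- names(eset)[i]
    L <- Biostrings::width(eset)[i]
    h <- search_hits(eset[i], mito$seq, params = params,
                     topology = mito$topology)
    h <- filter_hits(h, params$evalue_max, params$min_hit_length)
    if (nrow(h) == 0) { nomt <- c(nomt, id); next }
    # EST coverage by mito alignments (EST is the query here)
    ir <- IRanges::reduce(IRanges::IRanges(h$qstart, h$qend))
    cov <- sum(IRanges::width(ir)) / L
    hicov <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(h$qstart[h$pident >= pure_identity],
                       h$qend[h$pident >= pure_identity])))) / L
    if (cov >= pure_coverage && hicov >= pure_coverage) {
      pure <- c(pure, id)
      next
    }
    # contiguous non-mito block?
    gaps <- IRanges::gaps(ir, start = 1L, end = L)
    if (length(gaps) && max(IRanges::width(gaps)) >= min_flank) {
      chim <- c(chim, id)
      blocks[[id]] <- data.frame(
        est_id = id, est_start = h$qstart, est_end = h$qend,
        mito_chromosome = h$sseqid, mito_start = h$sstart,
        mito_end = h$send, strand = h$strand, identity = h$pident,
        evalue = h$evalue, stringsAsFactors = FALSE)
    } else {
      # mostly mito but below the pure thresholds: treat as pure filterable
      # only when coverage passes; otherwise keep with the non-chimeric rest
      nomt <- c(nomt, id)
    }
  }
  list(pure_mito = pure, chimeric = chim, no_mt = nomt,
       blocks = if (length(blocks)) do.call(rbind, blocks) else NULL)
}

#' Place a chimeric EST in the nuclear genome
#'
#' Aligns the full EST against the nuclear genome and accepts a placement
#' when at least `min_coverage` of the EST maps to a single locus (merged
#' overlapping/nearby hits on one scaffold). The placed mitochondrial block
#' is linked to an overlapping NUMT call when one exists, and the insertion
#' class is `utr5` when the mitochondrial block maps 5' of the host gene's
#' coding exons within the transcript span, `internal` otherwise;
#' `unplaced` when no locus passes. Equally scoring loci mark the placement
#' `ambiguous` (all loci listed, first reported).
#'
#' @param est_id,est_seq EST identifier and sequence.
#' @param genome nuclear `DNAStringSet` or [synthetic_genome].
#' @param numts NUMT calls from [call_numts()] (may be empty).
#' @param mt_blocks mitochondrial blocks for this EST from [screen_ests()].
#' @param annotation optional gene annotation (as in [classify_context()]);
#'   without it the class defaults to `internal`.
#' @param params [scoring_params()].
#' @param min_coverage EST fraction that must map to one locus (default
#'   0.9).
#' @return list with `placed`, `ambiguous`, `scaffold`, `start`, `end`,
#'   `linked_numt`, `insertion_class`, `host_gene`, `loci`.
#' @export
place_in_genome <- function(est_id, est_seq, genome, numts, mt_blocks = NULL,
                            annotation = NULL, params = scoring_params(),
                            min_coverage = 0.9) {
  ann <- annotation
  if (is(genome, "synthetic_genome")) {
    if (is.null(ann)) ann <- genome
    genome <- genome$nuclear
  }
  L <- nchar(as.character(est_seq))
  h <- search_hits(Biostrings::DNAStringSet(setNames(as.character(est_seq),
                                                     est_id)),
                   genome, params = params)
  h <- filter_hits(h, params$evalue_max, min_hit_length = 20L)
  res <- list(placed = FALSE, ambiguous = FALSE, scaffold = NA_character_,
              start = NA_integer_, end = NA_integer_,
              linked_numt = NA_character_, insertion_class = "unplaced",
              host_gene = NA_character_, loci = NULL)
  if (nrow(h) == 0) return(res)
  # cluster hits into loci: same scaffold, within 5 kb
  h <- h[order(h$sseqid, pmin(h$sstart, h$send)), , drop = FALSE]
  s1 <- pmin(h$sstart, h$send); s2 <- pmax(h$sstart, h$send)
  locus <- integer(nrow(h))
  locus[1] <- 1L
  maxend <- s2[1]
  if (nrow(h) > 1) {
    for (i in 2:nrow(h)) {
      if (h$sseqid[i] != h$sseqid[i - 1] || s1[i] - maxend > 5000L) {
        locus[i] <- locus[i - 1] + 1L
        maxend <- s2[i]
      } else {
        locus[i] <- locus[i - 1]
        maxend <- max(maxend, s2[i])
      }
    }
  }
  loci <- lapply(split(seq_len(nrow(h)), locus), function(ix) {
    cov <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(h$qstart[ix], h$qend[ix])))) / L
    data.frame(scaffold = h$sseqid[ix[1]], start = min(s1[ix]),
               end = max(s2[ix]), coverage = cov,
               score = sum(h$score[ix]), stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, loci)
  ok <- loci[loci$coverage >= min_coverage, , drop = FALSE]
  res$loci <- loci
  if (nrow(ok) == 0) return(res)
  ok <- ok[order(-ok$score), , drop = FALSE]
  res$placed <- TRUE
  res$ambiguous <- nrow(ok) > 1 && ok$score[2] == ok$score[1]
  res$scaffold <- ok$scaffold[1]
  res$start <- ok$start[1]
  res$end <- ok$end[1]

  # genomic interval of the EST's mito block at this locus
  mt_gen <- NULL
  if (!is.null(mt_blocks) && nrow(mt_blocks) > 0) {
    sel <- h$sseqid == res$scaffold & s1 >= res$start & s2 <= res$end
    hh <- h[sel, , drop = FALSE]
    for (b in seq_len(nrow(mt_blocks))) {
      ov <- which(hh$qstart <= mt_blocks$est_end[b] &
                    hh$qend >= mt_blocks$est_start[b])
      if (length(ov)) {
        mt_gen <- rbind(mt_gen, data.frame(
          start = min(pmin(hh$sstart, hh$send)[ov]),
          end = max(pmax(hh$sstart, hh$send)[ov])))
      }
    }
  }
  if (!is.null(mt_gen) && nrow(numts) > 0) {
    cand <- which(numts$nuclear_scaffold == res$scaffold &
                    numts$nuclear_start <= max(mt_gen$end) &
                    numts$nuclear_end >= min(mt_gen$start))
    if (length(cand)) res$linked_numt <- numts$numt_id[cand[1]]
  }

  res$insertion_class <- "internal"
  if (!is.null(ann) && !is.null(mt_gen)) {
    tab <- .gene_tables(ann)
    g <- tab$genes
    hit_g <- which(g$scaffold == res$scaffold &
                     g$start <= res$end + 500L & g$end >= res$start - 500L)
    if (length(hit_g)) {
      gi <- hit_g[1]
      res$host_gene <- g$gene_id[gi]
      cds_start <- if (g$strand[gi] == "+") g$start[gi] else g$end[gi]
      mt_mid <- (min(mt_gen$start) + max(mt_gen$end)) / 2
      upstream <- if (g$strand[gi] == "+") mt_mid < cds_start else {
        mt_mid > cds_start
      }
      if (upstream) res$insertion_class <- "utr5"
    }
  }
  res
}

#' Per-frame stop-codon report under a chosen genetic code
#'
#' Reports internal stop codons in all six reading frames under the
#' universal code or the mold/protozoan/coelenterate mitochondrial code
#' (NCBI translation table 4, where TGA encodes tryptophan). The terminal
#' codon of a frame is not counted as internal.
#'
#' @param sequence character/`DNAString`, length >= 3.
#' @param code_table `"universal"` or `"mold_mito"`.
#' @return `data.frame`: frame (`+1..+3`, `-1..-3`), n_codons,
#'   internal_stops, stop_positions (comma-separated codon indices),
#'   translatable (no internal stop).
#' @export
check_translation <- function(sequence, code_table = c("universal",
                                                       "mold_mito")) {
  code_table <- match.arg(code_table,
                          several.ok = FALSE)
  s <- toupper(as.character(sequence))
  if (nchar(s) < 3) stop("sequence must be at least 3 bp")
  gc_id <- if (code_table == "universal") "1" else "4"
  code <- Biostrings::getGeneticCode(gc_id)
  rc <- .revcomp(s)
  frames <- list(`+1` = substr(s, 1, nchar(s)),
                 `+2` = substr(s, 2, nchar(s)),
                 `+3` = substr(s, 3, nchar(s)),
                 `-1` = substr(rc, 1, nchar(rc)),
                 `-2` = substr(rc, 2, nchar(rc)),
                 `-3` = substr(rc, 3, nchar(rc)))
  rows <- lapply(names(frames), function(fn) {
    fs <- frames[[fn]]
    nc <- nchar(fs) %/% 3
    if (nc < 1) {
      return(data.frame(frame = fn, n_codons = 0L, internal_stops = 0L,
                        stop_positions = "", translatable = NA,
                        stringsAsFactors = FALSE))
    }
    codons <- substring(fs, 3 * (seq_len(nc) - 1) + 1, 3 * seq_len(nc))
    aa <- code[codons]
    aa[is.na(aa)] <- "X" # codons containing N are not stops
    stops <- which(aa == "*")
    internal <- stops[stops < nc]
    data.frame(frame = fn, n_codons = nc,
               internal_stops = length(internal),
               stop_positions = paste(internal, collapse = ","),
               translatable = length(internal) == 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expression screen over a full EST set
#'
#' Runs [screen_ests()], places every chimeric candidate with
#' [place_in_genome()], and attaches per-code stop-codon summaries of each
#' chimeric EST.
#'
#' @param ests `DNAStringSet` of ESTs.
#' @param mito [MitoGenome].
#' @param genome nuclear `DNAStringSet` or [synthetic_genome].
#' @param numts NUMT calls.
#' @param annotation optional annotation (see [place_in_genome()]).
#' @param params [scoring_params()].
#' @return list with `screen` (the [screen_ests()] partition) and `report`
#'   (`data.frame`: est_id, class, placement columns, stop-codon counts
#'   under both codes for the best frame).
#' @export
expression_screen <- function(ests, mito, genome, numts,
                              annotation = NULL,
                              params = scoring_params()) {
  eset <- .as_dna_set(ests, "est")
  scr <- screen_ests(eset, mito, params = params)
  rows <- list()
  for (id in scr$chimeric) {
    blk <- scr$blocks[scr$blocks$est_id == id, , drop = FALSE]
    pl <- place_in_genome(id, as.character(eset[[id]]), genome, numts,
                          mt_blocks = blk, annotation = annotation,
                          params = params)
    tr <- check_translation(as.character(eset[[id]]), "universal")
    tr4 <- check_translation(as.character(eset[[id]]), "mold_mito")
    rows[[length(rows) + 1L]] <- data.frame(
      est_id = id, class = "chimeric",
      placed = pl$placed, ambiguous = pl$ambiguous,
      scaffold = pl$scaffold, start = pl$start, end = pl$end,
      linked_numt = pl$linked_numt, insertion_class = pl$insertion_class,
      host_gene = pl$host_gene,
      min_stops_universal = min(tr$internal_stops),
      min_stops_mito = min(tr4$internal_stops),
      stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) do.call(rbind, rows) else data.frame(
    est_id = character(), class = character(), placed = logical(),
    ambiguous = logical(), scaffold = character(), start = integer(),
    end = integer(), linked_numt = character(),
    insertion_class = character(), host_gene = character(),
    min_stops_universal = integer(), min_stops_mito = integer(),
    stringsAsFactors = FALSE)
  list(screen = scr, report = report)
}
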