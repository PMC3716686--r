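# Genomic context of NUMTs: gene density around each insertion and precise
# localization within gene models.

# normalize gene/exon input (synthetic_genome, data.frame, or GRanges)
.gene_tables <- function(annotation) {
  if (is(annotation, "synthetic_genome")) {
    genes <- data.frame(gene_id = annotation$genes$gene_id,
                        scaffold = annotation$genes$scaffold,
                        strand = annotation$genes$strand,
                        start = annotation$genes$final_start,
                        end = annotation$genes$final_end,
                        stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = annotation$exons$gene_id,
                        scaffold = annotation$exons$scaffold,
                        strand = annotation$exons$strand,
                        exon_rank = annotation$exons$exon_rank,
                        start = annotation$exons$final_start,
                        end = annotation$exons$final_end,
                        stringsAsFactors = FALSE)
    return(list(genes = genes, exons = exons))
  }
  if (is.list(annotation) && all(c("genes", "exons") %in% names(annotation))) {
    return(annotation[c("genes", "exons")])
  }
  stop("annotation must be a synthetic_genome or list(genes=, exons=)")
}

#' Classify gene density around each NUMT
#'
#' Counts annotated genes whose span intersects a window around the NUMT
#' (the NUMT interval padded by `window_bp / 2` on each side, clipped to
#' the scaffold) and maps the count to the three density categories:
#' `non_genic` (0 genes), `low_density` (1-2), `high_density` (> 2).
#'
#' @param numts NUMT calls from [call_numts()] (or the truth ledger with
#'   matching column names).
#' @param genes gene table (`gene_id`, `scaffold`, `start`, `end`).
#' @param window_bp total window padding in bp (default 10,000: 5 kb per
#'   side).
#' @return `data.frame`: numt_id, genes_in_window, density.
#' @export
classify_density <- function(numts, genes, window_bp = 10000L) {
  if (nrow(numts) == 0) {
    return(data.frame(numt_id = character(), genes_in_window = integer(),
                      density = character(), stringsAsFactors = FALSE))
  }
  half <- window_bp %/% 2L
  win <- GenomicRanges::GRanges(
    numts$nuclear_scaffold,
    IRanges::IRanges(pmax(1L, numts$nuclear_start - half),
                     numts$nuclear_end + half))
  gg <- GenomicRanges::GRanges(genes$scaffold,
                               IRanges::IRanges(genes$start, genes$end))
  cnt <- GenomicRanges::countOverlaps(win, gg)
  data.frame(
    numt_id = numts$numt_id,
    genes_in_window = as.integer(cnt),
    density = ifelse(cnt == 0, "non_genic",
                     ifelse(cnt <= 2, "low_density", "high_density")),
    stringsAsFactors = FALSE)
}

#' Locate a NUMT within one gene model
#'
#' Returns the feature the NUMT occupies in the gene: `exon` if it overlaps
#' any exon (exon overlap dominates), `intron_i` if it lies wholly within
#' the i-th intron counted in transcription order (1..n-1), `utr5`/`utr3`
#' when UTR intervals are annotated and the NUMT lies wholly within one,
#' otherwise `intergenic`. Orientation is the strand comparison between the
#' NUMT and the host gene.
#'
#' @param numt one NUMT row (needs `nuclear_start`, `nuclear_end`,
#'   `strand`).
#' @param gene_model list with `strand`, `exons` (`data.frame` with
#'   `start`, `end`), optional `utr5`/`utr3` intervals (`c(start, end)`).
#' @return list with `feature` and `same_orientation`.
#' @export
locate_in_gene <- function(numt, gene_model) {
  ex <- gene_model$exons[order(gene_model$exons$start), , drop = FALSE]
  if (nrow(ex) > 1 &&
      any(ex$start[-1] <= ex$end[-nrow(ex)])) {
    stop("annotation error: overlapping exons in gene model",
         if (!is.null(gene_model$gene_id)) paste0(" ", gene_model$gene_id))
  }
  s <- numt$nuclear_start; e <- numt$nuclear_end
  same <- if (!is.null(numt$strand) && !is.null(gene_model$strand)) {
    numt$strand == gene_model$strand
  } else NA
  # any exon overlap dominates
  if (any(s <= ex$end & e >= ex$start)) {
    return(list(feature = "exon", same_orientation = same))
  }
  for (utr in c("utr5", "utr3")) {
    u <- gene_model[[utr]]
    if (!is.null(u) && s >= u[1] && e <= u[2]) {
      return(list(feature = utr, same_orientation = same))
    }
  }
  if (nrow(ex) >= 2) {
    for (k in seq_len(nrow(ex) - 1L)) {
      if (s > ex$end[k] && e < ex$start[k + 1L]) {
        i <- if (gene_model$strand == "+") k else nrow(ex) - k
        return(list(feature = sprintf("intron_%d", i),
                    same_orientation = same))
      }
    }
  }
  list(feature = "intergenic", same_orientation = same)
}

#' Full genomic-context classification of NUMT calls
#'
#' Combines [classify_density()] with per-gene localization: a NUMT
#' overlapping one or more gene spans is assigned to the gene with the
#' largest overlap (ties broken by lexicographic gene id) and located
#' within it with [locate_in_gene()].
#'
#' @param numts NUMT calls from [call_numts()].
#' @param annotation a [synthetic_genome] or `list(genes=, exons=)` (see
#'   [classify_density()] for the gene table; exons need `gene_id`,
#'   `scaffold`, `strand`, `exon_rank`, `start`, `end`).
#' @param window_bp density window (default 10,000).
#' @return `data.frame`: numt_id, genes_in_window, density, host_gene,
#'   feature, same_orientation_as_host.
#' @export
classify_context <- function(numts, annotation, window_bp = 10000L) {
  tab <- .gene_tables(annotation)
  genes <- tab$genes; exons <- tab$exons
  dens <- classify_density(numts, genes, window_bp)
  host <- rep(NA_character_, nrow(numts))
  feat <- rep("intergenic", nrow(numts))
  orient <- rep(NA, nrow(numts))
  if (nrow(numts) > 0 && nrow(genes) > 0) {
    ngr <- GenomicRanges::GRanges(
      numts$nuclear_scaffold,
      IRanges::IRanges(numts$nuclear_start, numts$nuclear_end))
    ggr <- GenomicRanges::GRanges(genes$scaffold,
                                  IRanges::IRanges(genes$start, genes$end))
    ov <- GenomicRanges::findOverlaps(ngr, ggr)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      ovw <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(ngr)[qh], IRanges::ranges(ggr)[sh]))
      for (i in unique(qh)) {
        cand <- which(qh == i)
        # largest overlap, ties by lexicographic gene id
        o <- cand[order(-ovw[cand], genes$gene_id[sh[cand]])][1]
        gid <- genes$gene_id[sh[o]]
        gm <- list(gene_id = gid,
                   strand = genes$strand[genes$gene_id == gid],
                   exons = exons[exons$gene_id == gid,
                                 c("start", "end"), drop = FALSE])
        gm$exons <- gm$exons[order(gm$exons$start), , drop = FALSE]
        loc <- locate_in_gene(numts[i, ], gm)
        host[i] <- gid
        feat[i] <- loc$feature
        orient[i] <- loc$same_orientation
        if (loc$feature == "intergenic") host[i] <- NA_character_
      }
    }
  }
  cbind(dens, data.frame(host_gene = host, feature = feat,
                         same_orientation_as_host = orient,
                         stringsAsFactors = FALSE))
}
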