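# Readers and writers for the standard interchange formats of the pipeline.

#' Write alignment hits as BLAST outfmt-6-compatible TSV
#'
#' Columns `qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore`, 1-based closed coordinates; minus-strand hits are
#' written with `sstart > send`.
#'
#' @param hits hit table from [search_hits()].
#' @param path output file.
#' @param header write a commented header line (default FALSE, like BLAST).
#' @export
write_hits_tsv <- function(hits, path, header = FALSE) {
  out <- hits[, c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")]
  minus <- hits$strand == "-"
  tmp <- out$sstart[minus]
  out$sstart[minus] <- out$send[minus]
  out$send[minus] <- tmp
  if (header) {
    writeLines(paste0("# ", paste(names(out), collapse = "\t")), path)
    suppressWarnings(write.table(out, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, col.names = FALSE,
                                 append = TRUE))
  } else {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Read an outfmt-6-style hit TSV back into the hit-table layout
#'
#' Inverse of [write_hits_tsv()]: `sstart > send` is decoded as minus
#' strand and coordinates are normalized to ascending.
#'
#' @param path TSV file.
#' @return hit `data.frame` (without raw score/gap columns).
#' @export
read_hits_tsv <- function(path) {
  h <- read.table(path, sep = "\t", comment.char = "#",
                  col.names = c("qseqid", "sseqid", "pident", "length",
                                "mismatch", "gapopen", "qstart", "qend",
                                "sstart", "send", "evalue", "bitscore"),
                  stringsAsFactors = FALSE)
  h$strand <- ifelse(h$sstart > h$send, "-", "+")
  s1 <- pmin(h$sstart, h$send); s2 <- pmax(h$sstart, h$send)
  h$sstart <- s1; h$send <- s2
  h$wraps_origin <- FALSE
  h
}

#' Write NUMT calls as BED6
#'
#' 0-based half-open intervals; the score column carries the bit score,
#' the name column the NUMT id.
#'
#' @param numts NUMT calls from [call_numts()].
#' @param path output file.
#' @export
write_numts_bed <- function(numts, path) {
  bed <- data.frame(chrom = numts$nuclear_scaffold,
                    start = numts$nuclear_start - 1L,
                    end = numts$nuclear_end,
                    name = numts$numt_id,
                    score = round(numts$bitscore),
                    strand = numts$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write the truth ledger as BED6
#'
#' 0-based half-open nuclear intervals, name = insertion id.
#' @param ledger truth ledger from [generate_nuclear_genome()].
#' @param path output file.
#' @export
write_ledger_bed <- function(ledger, path) {
  bed <- data.frame(chrom = ledger$nuclear_scaffold,
                    start = ledger$nuclear_start - 1L,
                    end = ledger$nuclear_end,
                    name = ledger$id, score = 0L, strand = ledger$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Export planted gene models as GFF3
#'
#' Writes `gene`/`mRNA`/`exon`/`CDS` features (1-based closed) for a
#' synthetic genome via rtracklayer.
#'
#' @param genome a [synthetic_genome].
#' @param path output GFF3 file.
#' @export
write_genes_gff3 <- function(genome, path) {
  stopifnot(is(genome, "synthetic_genome"))
  g <- genome$genes; e <- genome$exons
  feats <- list()
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    ex <- e[e$gene_id == gid, , drop = FALSE]
    feats[[length(feats) + 1L]] <- data.frame(
      seqnames = c(g$scaffold[i], g$scaffold[i], ex$scaffold, ex$scaffold),
      start = c(g$final_start[i], g$final_start[i], ex$final_start,
                ex$final_start),
      end = c(g$final_end[i], g$final_end[i], ex$final_end, ex$final_end),
      strand = c(g$strand[i], g$strand[i], ex$strand, ex$strand),
      type = c("gene", "mRNA", rep("exon", nrow(ex)),
               rep("CDS", nrow(ex))),
      ID = c(gid, paste0(gid, ".t1"),
             paste0(gid, ".t1.exon", ex$exon_rank),
             paste0(gid, ".t1.cds", ex$exon_rank)),
      Parent = c(NA, gid, rep(paste0(gid, ".t1"), 2 * nrow(ex))),
      stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(d$seqnames,
                               IRanges::IRanges(d$start, d$end),
                               strand = d$strand)
  S4Vectors::mcols(gr)$type <- d$type
  S4Vectors::mcols(gr)$ID <- d$ID
  S4Vectors::mcols(gr)$Parent <- d$Parent
  S4Vectors::mcols(gr)$phase <- ifelse(d$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from a GFF3 file into the annotation layout
#'
#' Parses `gene` and `exon` features (1-based closed) into the
#' `list(genes=, exons=)` layout used by [classify_context()]. Exon ranks
#' are assigned in transcription order per gene.
#'
#' @param path GFF3 file.
#' @return list with `genes` and `exons` data frames.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  genes <- data.frame(
    gene_id = as.character(md$ID[is_gene]),
    scaffold = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    stringsAsFactors = FALSE)
  is_ex <- md$type == "exon"
  parent <- vapply(md$Parent[is_ex], function(p) {
    if (length(p)) as.character(p[1]) else NA_character_
  }, "")
  gid <- sub("\\.t[0-9]+$", "", parent)
  exons <- data.frame(
    gene_id = gid,
    scaffold = as.character(GenomicRanges::seqnames(gr)[is_ex]),
    strand = as.character(GenomicRanges::strand(gr)[is_ex]),
    start = GenomicRanges::start(gr)[is_ex],
    end = GenomicRanges::end(gr)[is_ex],
    stringsAsFactors = FALSE)
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  exons$exon_rank <- stats::ave(seq_len(nrow(exons)), exons$gene_id,
                                FUN = function(ix) {
                                  st <- exons$strand[ix[1]]
                                  if (st == "-") rev(seq_along(ix))
                                  else seq_along(ix)
                                })
  list(genes = genes, exons = exons)
}

#' Write the truth ledger as JSON
#' @param ledger truth ledger `data.frame`.
#' @param path output file.
#' @export
write_ledger_json <- function(ledger, path) {
  jsonlite::write_json(ledger, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}
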