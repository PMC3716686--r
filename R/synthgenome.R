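# Synthetic genomes with planted NUMT insertions and a machine-readable
# truth ledger, so every downstream stage is testable without external data.

.BASES <- c("A", "C", "G", "T")

# deterministic sub-stream seeds derived from one master seed (kept < 2^31)
.substream <- function(seed, k) {
  as.integer((as.double(seed) %% 65536) * 31013 + 7919 * k + 1) %% 2147483647L
}

.random_dna <- function(n, gc) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Apply substitutions and indels; indel lengths are geometric (p = 0.5,
# capped at 10 bp). Returns the mutated sequence and the realized
# substitution count (used by the divergence-calibration tests).
.mutate_seq <- function(s, subst_rate, indel_rate) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  nsub <- if (subst_rate > 0) rbinom(1, n, subst_rate) else 0L
  if (nsub > 0) {
    pos <- sample.int(n, nsub)
    v[pos] <- vapply(v[pos],
                     function(b) sample(setdiff(.BASES, b), 1), "")
  }
  nind <- if (indel_rate > 0) rbinom(1, n, indel_rate) else 0L
  if (nind > 0) {
    for (p in sort(sample.int(max(n - 1, 1), min(nind, n - 1)),
                   decreasing = TRUE)) {
      len <- min(rgeom(1, 0.5) + 1L, 10L)
      if (runif(1) < 0.5) { # insertion after p
        v <- append(v, sample(.BASES, len, replace = TRUE), after = p)
      } else { # deletion starting at p
        v <- v[-(p:min(p + len - 1L, length(v)))]
      }
    }
  }
  list(seq = paste(v, collapse = ""), n_subst = nsub)
}

#' Configuration for the synthetic-genome simulator
#'
#' The defaults state a scaled-down hydrozoan-like world: a linear
#' mitochondrial genome split over two chromosomes of 8,194 and 7,686 bp
#' with identical inverted terminal repeats (ITRs), an AT-rich nuclear
#' genome, and NUMT insertions whose lengths and divergences span the ranges
#' reported for recent-to-old insertions.
#'
#' @param seed master RNG seed; all sub-streams derive from it
#'   deterministically (identical seed + config gives byte-identical output).
#' @param nuclear_length total nuclear genome size in bp.
#' @param n_scaffolds number of nuclear scaffolds the genome is split into.
#' @param gc_content background GC fraction in `[0, 1]`.
#' @param n_genes number of planted protein-coding gene models.
#' @param mito_topology `"linear"` or `"circular"`.
#' @param n_mito_chromosomes 1 or 2 (2 only for linear topology).
#' @param mito_lengths chromosome lengths in bp (sum must be >= 1,000).
#' @param itr_length inverted-terminal-repeat length in bp (linear only;
#'   must be < `min(mito_lengths) / 2`).
#' @param intron_in_nd5 whether the mitochondrial ND5 gene carries a group-I
#'   intron (circular anthozoan-like genomes).
#' @param n_insertions number of planted NUMT insertions.
#' @param insertion_length_dist list `(min, max, shape)` of insertion
#'   lengths; `shape` is `"uniform"` or `"loguniform"`.
#' @param divergence_dist list `(min, max, indel_frac)`: per-insertion
#'   substitution rate drawn uniformly from `[min, max]` (each must lie in
#'   `[0, 0.3]`); the indel rate is `indel_frac` times the substitution rate.
#' @param duplication_spec list of `c(family_size, count)` pairs; each family
#'   is one mutated insertion copied to `family_size` distinct loci.
#'   `sum(family_size * count)` insertions count against `n_insertions`.
#' @param n_interrupted number of insertions split by an interposed element.
#' @param interruption_kind_probs named probabilities for
#'   `low_complexity` / `te` interruption elements.
#' @param n_intronic number of insertions placed wholly inside introns (all
#'   insertions sharing one host gene get the same orientation).
#' @param est_spec named counts of transcripts to simulate:
#'   `pure_mito`, `chimeric_utr5`, `chimeric_internal`, `plain_nuclear`.
#' @param est_error_rate per-base error applied to simulated ESTs.
#' @return validated object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       nuclear_length = 1000000L,
                       n_scaffolds = 4L,
                       gc_content = 0.276,
                       n_genes = 40L,
                       mito_topology = c("linear", "circular"),
                       n_mito_chromosomes = 2L,
                       mito_lengths = c(8194L, 7686L),
                       itr_length = 150L,
                       intron_in_nd5 = FALSE,
                       n_insertions = 50L,
                       insertion_length_dist = list(min = 100L, max = 2000L,
                                                    shape = "uniform"),
                       divergence_dist = list(min = 0, max = 0.15,
                                              indel_frac = 0.1),
                       duplication_spec = list(),
                       n_interrupted = 0L,
                       interruption_kind_probs = c(low_complexity = 0.5,
                                                   te = 0.5),
                       n_intronic = 0L,
                       est_spec = c(pure_mito = 0L, chimeric_utr5 = 0L,
                                    chimeric_internal = 0L,
                                    plain_nuclear = 0L),
                       est_error_rate = 0.005) {
  mito_topology <- match.arg(mito_topology)
  if (mito_topology == "circular" && n_mito_chromosomes != 1) {
    stop("configuration error: circular topology requires a single ",
         "mitochondrial chromosome")
  }
  if (!n_mito_chromosomes %in% c(1L, 2L)) {
    stop("configuration error: n_mito_chromosomes must be 1 or 2")
  }
  if (length(mito_lengths) != n_mito_chromosomes) {
    stop("configuration error: mito_lengths must have n_mito_chromosomes ",
         "entries")
  }
  if (sum(mito_lengths) < 1000) {
    stop("configuration error: mitochondrial genome must total >= 1,000 bp")
  }
  if (mito_topology == "linear" && itr_length >= min(mito_lengths) / 2) {
    stop("configuration error: itr_length must be < min(mito_lengths)/2")
  }
  if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0,1]")
  if (divergence_dist$min < 0 || divergence_dist$max > 0.3) {
    stop("configuration error: divergence must lie in [0, 0.3]")
  }
  n_dup <- if (length(duplication_spec)) {
    sum(vapply(duplication_spec, function(x) x[1] * x[2], 0))
  } else 0
  est <- c(pure_mito = 0L, chimeric_utr5 = 0L, chimeric_internal = 0L,
           plain_nuclear = 0L)
  est[names(est_spec)] <- as.integer(est_spec)
  reserved <- n_dup + n_interrupted + n_intronic + est[["chimeric_utr5"]]
  if (reserved > n_insertions) {
    stop("configuration error: duplications + interrupted + intronic + ",
         "5'-UTR insertions exceed n_insertions")
  }
  if (n_intronic > n_insertions) {
    stop("configuration error: n_intronic exceeds n_insertions")
  }
  structure(
    list(seed = as.integer(seed), nuclear_length = as.integer(nuclear_length),
         n_scaffolds = as.integer(n_scaffolds), gc_content = gc_content,
         n_genes = as.integer(n_genes), mito_topology = mito_topology,
         n_mito_chromosomes = as.integer(n_mito_chromosomes),
         mito_lengths = as.integer(mito_lengths),
         itr_length = as.integer(itr_length),
         intron_in_nd5 = isTRUE(intron_in_nd5),
         n_insertions = as.integer(n_insertions),
         insertion_length_dist = insertion_length_dist,
         divergence_dist = divergence_dist,
         duplication_spec = duplication_spec,
         n_interrupted = as.integer(n_interrupted),
         interruption_kind_probs = interruption_kind_probs,
         n_intronic = as.integer(n_intronic),
         est_spec = est, est_error_rate = est_error_rate),
    class = "sim_config")
}

# mitochondrial gene complement used for the placeholder annotation
.MITO_GENES <- list(
  pc = c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
         "COX1", "COX2", "COX3", "ATP6", "ATP8", "CYTB"),
  rrna = c("s-rRNA", "l-rRNA"),
  trna = c("tRNA-Met", "tRNA-Trp"))

#' Generate a mitochondrial genome
#'
#' Builds one or two mitochondrial chromosomes of the requested lengths with
#' a placeholder gene annotation (13 protein-coding genes, 2 rRNAs, 2
#' tRNAs). For a two-chromosome linear genome both chromosomes carry an
#' identical inverted terminal repeat (ITR) of `itr_length` at each end.
#' With `intron_in_nd5` the ND5 gene is split by a group-I-style intron
#' whose interval is recorded.
#'
#' @param config a [sim_config()] object.
#' @return object of class `MitoGenome`: named `DNAStringSet` `seq`,
#'   `topology`, `itr_length`, `total_length`, annotation `data.frame`
#'   (chrom, type, gene, start, end, strand), and `nd5_intron` (or `NULL`).
#' @export
generate_mito_genome <- function(config) {
  stopifnot(is(config, "sim_config"))
  set.seed(.substream(config$seed, 1L))
  nchr <- config$n_mito_chromosomes
  lens <- config$mito_lengths
  itr <- if (config$mito_topology == "linear") config$itr_length else 0L
  itr_seq <- if (itr > 0) .random_dna(itr, config$gc_content) else ""

  chroms <- character(nchr)
  for (i in seq_len(nchr)) {
    core <- .random_dna(lens[i] - 2L * itr, config$gc_content)
    chroms[i] <- if (itr > 0) {
      paste0(itr_seq, core, .revcomp(itr_seq))
    } else core
  }
  names(chroms) <- if (nchr == 2) c("mt-Chr1", "mt-Chr2") else "chrM"

  # distribute the gene complement across chromosomes by core length
  genes <- c(.MITO_GENES$pc, .MITO_GENES$rrna, .MITO_GENES$trna)
  types <- c(rep("protein_coding", 13), rep("rRNA", 2), rep("tRNA", 2))
  assign_chr <- if (nchr == 2) {
    n1 <- round(length(genes) * lens[1] / sum(lens))
    c(rep(1L, n1), rep(2L, length(genes) - n1))
  } else rep(1L, length(genes))

  ann <- list()
  nd5_intron <- NULL
  for (ci in seq_len(nchr)) {
    idx <- which(assign_chr == ci)
    if (!length(idx)) next
    lo <- itr + 1L
    hi <- lens[ci] - itr
    avail <- hi - lo + 1L
    w <- ifelse(types[idx] == "tRNA", 0.05,
                ifelse(types[idx] == "rRNA", 2, 1))
    spacer <- 20L
    widths <- pmax(60L, floor((avail - spacer * length(idx)) * w / sum(w)))
    start <- lo
    for (k in seq_along(idx)) {
      g <- genes[idx[k]]
      if (start >= hi) break
      end <- min(start + widths[k] - 1L, hi)
      strand <- sample(c("+", "-"), 1)
      if (g == "ND5" && config$intron_in_nd5) {
        span <- end - start + 1L
        i1 <- start + floor(span * 0.3)
        i2 <- start + floor(span * 0.7)
        nd5_intron <- data.frame(chrom = names(chroms)[ci],
                                 start = i1, end = i2)
        ann[[length(ann) + 1L]] <- data.frame(
          chrom = names(chroms)[ci],
          type = c("gene", "exon", "intron", "exon"),
          gene = g, start = c(start, start, i1, i2 + 1L),
          end = c(end, i1 - 1L, i2, end), strand = strand,
          stringsAsFactors = FALSE)
      } else {
        ann[[length(ann) + 1L]] <- data.frame(
          chrom = names(chroms)[ci], type = "gene", gene = g,
          start = start, end = end, strand = strand,
          stringsAsFactors = FALSE)
      }
      start <- end + spacer + 1L
    }
  }
  structure(
    list(seq = Biostrings::DNAStringSet(chroms),
         topology = config$mito_topology,
         itr_length = itr, total_length = sum(lens),
         annotation = do.call(rbind, ann), nd5_intron = nd5_intron),
    class = "MitoGenome")
}

#' @export
print.MitoGenome <- function(x, ...) {
  cat(sprintf("MitoGenome: %d chromosome(s), %s, %d bp total\n",
              length(x$seq), x$topology, x$total_length))
  for (i in seq_along(x$seq)) {
    cat(sprintf("  %s: %d bp\n", names(x$seq)[i],
                Biostrings::width(x$seq)[i]))
  }
  if (x$itr_length > 0) cat(sprintf("  ITR: %d bp\n", x$itr_length))
  invisible(x)
}

# sample an insertion length from the configured distribution
.sample_ins_len <- function(d) {
  if (identical(d$shape, "loguniform")) {
    as.integer(round(exp(runif(1, log(d$min), log(d$max)))))
  } else {
    as.integer(round(runif(1, d$min, d$max)))
  }
}

# extract a (possibly origin-wrapping) mitochondrial segment
.mito_segment <- function(mito, chrom, start, len) {
  s <- mito$seq[[chrom]]
  L <- length(s)
  end <- start + len - 1L
  if (end <= L) {
    as.character(Biostrings::subseq(s, start, end))
  } else { # circular wrap
    paste0(as.character(Biostrings::subseq(s, start, L)),
           as.character(Biostrings::subseq(s, 1L, end - L)))
  }
}

#' Generate a nuclear genome with planted NUMTs and a truth ledger
#'
#' Lays down i.i.d. background sequence at the configured GC over
#' `n_scaffolds` scaffolds, plants multi-exon gene models, and inserts
#' mutated copies of mitochondrial segments: plain intergenic insertions,
#' post-insertion duplication families (one mutated copy placed at several
#' loci), insertions split by an interposed low-complexity or
#' transposable-element sequence, intronic insertions (one orientation per
#' host gene), and insertions just upstream of genes to support chimeric
#' 5'-UTR transcripts. Everything planted is recorded in the ledger.
#'
#' @param config a [sim_config()] object.
#' @param mito the [generate_mito_genome()] output for the same config.
#' @return object of class `synthetic_genome`: `nuclear` (`DNAStringSet`),
#'   `genes` (gene table), `exons` (exon table, final coordinates),
#'   `ledger` (truth `data.frame`, 1-based closed nuclear/mito intervals),
#'   `repeat_library` (`DNAStringSet` of TE elements used), and the config.
#' @export
generate_nuclear_genome <- function(config, mito) {
  stopifnot(is(config, "sim_config"), is(mito, "MitoGenome"))
  set.seed(.substream(config$seed, 2L))

  nsc <- config$n_scaffolds
  base_len <- config$nuclear_length %/% nsc
  sc_len <- rep(base_len, nsc)
  sc_len[nsc] <- sc_len[nsc] + config$nuclear_length %% nsc
  sc_names <- sprintf("scaffold_%d", seq_len(nsc))

  # --- gene models on background coordinates -------------------------------
  genes <- data.frame(gene_id = character(), scaffold = character(),
                      strand = character(), start = integer(),
                      end = integer(), n_exons = integer(),
                      stringsAsFactors = FALSE)
  exons <- list()
  occupied <- lapply(sc_len, function(l) IRanges::IRanges())
  names(occupied) <- sc_names
  for (g in seq_len(config$n_genes)) {
    ne <- sample(2:8, 1)
    ew <- sample(100:400, ne, replace = TRUE)
    iw <- sample(200:2000, ne - 1, replace = TRUE)
    span <- sum(ew) + sum(iw)
    placed <- FALSE
    for (att in 1:200) {
      sc <- sample(nsc, 1, prob = sc_len)
      if (span + 1000 >= sc_len[sc]) next
      st <- sample.int(sc_len[sc] - span - 1000L, 1) + 500L
      cand <- IRanges::IRanges(st - 200L, st + span + 200L)
      if (length(IRanges::findOverlaps(cand, occupied[[sc]])) == 0) {
        occupied[[sc]] <- c(occupied[[sc]], cand)
        gid <- sprintf("gene%03d", g)
        strand <- sample(c("+", "-"), 1)
        genes <- rbind(genes, data.frame(
          gene_id = gid, scaffold = sc_names[sc], strand = strand,
          start = st, end = st + span - 1L, n_exons = ne,
          stringsAsFactors = FALSE))
        es <- st
        for (e in seq_len(ne)) {
          exons[[length(exons) + 1L]] <- data.frame(
            gene_id = gid, scaffold = sc_names[sc], strand = strand,
            exon_rank = if (strand == "+") e else ne - e + 1L,
            start = es, end = es + ew[e] - 1L, stringsAsFactors = FALSE)
          es <- es + ew[e] + if (e < ne) iw[e] else 0L
        }
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("placement error: could not place gene models without overlap; ",
           "increase nuclear_length or reduce n_genes")
    }
  }
  exons <- do.call(rbind, exons)

  # --- roles of the planted insertions -------------------------------------
  n_ins <- config$n_insertions
  roles <- rep("plain", n_ins)
  fam_id <- rep(NA_character_, n_ins)
  k <- 1L
  fam_counter <- 0L
  if (length(config$duplication_spec)) {
    for (fs in config$duplication_spec) {
      for (rep_i in seq_len(fs[2])) {
        fam_counter <- fam_counter + 1L
        idx <- k:(k + fs[1] - 1L)
        roles[idx] <- "family"
        fam_id[idx] <- sprintf("fam%03d", fam_counter)
        k <- k + fs[1]
      }
    }
  }
  take <- function(n, role) {
    idx <- which(roles == "plain")[seq_len(n)]
    roles[idx] <<- role
    idx
  }
  if (config$n_interrupted > 0) take(config$n_interrupted, "interrupted")
  if (config$n_intronic > 0) take(config$n_intronic, "intronic")
  n_utr5 <- config$est_spec[["chimeric_utr5"]]
  if (n_utr5 > 0) take(n_utr5, "utr5")

  # --- mitochondrial origins and mutated sequences -------------------------
  mlen <- Biostrings::width(mito$seq)
  mnames <- names(mito$seq)
  circular <- mito$topology == "circular"
  ins <- vector("list", n_ins)
  fam_cache <- list()
  for (i in seq_len(n_ins)) {
    if (!is.na(fam_id[i]) && !is.null(fam_cache[[fam_id[i]]])) {
      ins[[i]] <- fam_cache[[fam_id[i]]] # identical copy at a new locus
      next
    }
    ci <- sample(length(mlen), 1, prob = mlen)
    len <- max(60L, min(.sample_ins_len(config$insertion_length_dist),
                        mlen[ci] - 2L))
    start <- if (circular) sample.int(mlen[ci], 1) else {
      sample.int(mlen[ci] - len + 1L, 1)
    }
    wraps <- circular && (start + len - 1L > mlen[ci])
    div <- runif(1, config$divergence_dist$min, config$divergence_dist$max)
    seg <- .mito_segment(mito, ci, start, len)
    mut <- .mutate_seq(seg, div, div * config$divergence_dist$indel_frac)
    strand <- sample(c("+", "-"), 1)
    rec <- list(mito_chromosome = mnames[ci], mito_start = start,
                mito_end = start + len - 1L, wraps_origin = wraps,
                strand = strand, divergence = div, n_subst = mut$n_subst,
                seq_plus = mut$seq)
    ins[[i]] <- rec
    if (!is.na(fam_id[i])) fam_cache[[fam_id[i]]] <- rec
  }

  # --- repeat/TE library and interruption elements -------------------------
  te_lib <- Biostrings::DNAStringSet(setNames(
    vapply(sample(500:1500, 3, replace = TRUE),
           function(l) .random_dna(l, config$gc_content), ""),
    sprintf("TE_%d", 1:3)))

  interruption <- vector("list", n_ins)
  for (i in which(roles == "interrupted")) {
    kind <- sample(names(config$interruption_kind_probs), 1,
                   prob = config$interruption_kind_probs)
    if (kind == "low_complexity") {
      unit <- paste(sample(.BASES, 2), collapse = "")
      elem <- paste(rep(unit, sample(100:400, 1)), collapse = "")
    } else {
      te <- as.character(te_lib[[sample(3, 1)]])
      elem <- .mutate_seq(te, 0.02, 0.002)$seq
    }
    interruption[[i]] <- list(kind = kind, elem = elem)
  }

  # --- insertion points on background coordinates --------------------------
  # (insertions are spliced in; distinct points can never overlap)
  genes_with_introns <- genes$gene_id[genes$n_exons >= 2]
  pts <- data.frame(idx = integer(), scaffold = character(),
                    point = integer(), host_gene = character(),
                    host_feature = character(), stringsAsFactors = FALSE)
  used_pts <- lapply(sc_len, function(l) integer())
  names(used_pts) <- sc_names

  gene_orient <- list() # one orientation per intronic host gene
  intronic_idx <- which(roles == "intronic")
  if (length(intronic_idx)) {
    if (!length(genes_with_introns)) {
      stop("placement error: intronic insertions requested but no gene ",
           "has an intron")
    }
    hosts <- sample(genes_with_introns, length(intronic_idx), replace = TRUE)
    for (h in seq_along(intronic_idx)) {
      i <- intronic_idx[h]
      gid <- hosts[h]
      ex <- exons[exons$gene_id == gid, ]
      ex <- ex[order(ex$start), ]
      intr_no <- sample(nrow(ex) - 1L, 1)
      lo <- ex$end[intr_no] + 10L
      hi <- ex$start[intr_no + 1L] - 10L
      p <- sample(lo:hi, 1)
      sc <- ex$scaffold[1]
      if (is.null(gene_orient[[gid]])) {
        gene_orient[[gid]] <- sample(c("+", "-"), 1)
      }
      ins[[i]]$strand <- gene_orient[[gid]] # one orientation per host gene
      pts <- rbind(pts, data.frame(
        idx = i, scaffold = sc, point = p, host_gene = gid,
        host_feature = sprintf("intron_%d",
                               .intron_rank(ex, intr_no)),
        stringsAsFactors = FALSE))
      used_pts[[sc]] <- c(used_pts[[sc]], p)
    }
  }

  utr5_idx <- which(roles == "utr5")
  if (length(utr5_idx)) {
    cand_genes <- setdiff(genes$gene_id, pts$host_gene)
    if (length(cand_genes) < length(utr5_idx)) {
      stop("placement error: not enough genes for 5'-UTR insertions")
    }
    hosts <- sample(cand_genes, length(utr5_idx))
    for (h in seq_along(utr5_idx)) {
      i <- utr5_idx[h]
      grow <- genes[genes$gene_id == hosts[h], ]
      p <- if (grow$strand == "+") grow$start - sample(50:200, 1) else {
        grow$end + sample(50:200, 1)
      }
      pts <- rbind(pts, data.frame(
        idx = i, scaffold = grow$scaffold, point = p,
        host_gene = grow$gene_id, host_feature = "utr5",
        stringsAsFactors = FALSE))
      used_pts[[grow$scaffold]] <- c(used_pts[[grow$scaffold]], p)
    }
  }

  other_idx <- which(!seq_len(n_ins) %in% pts$idx)
  for (i in other_idx) {
    placed <- FALSE
    for (att in 1:500) {
      sc <- sample(nsc, 1, prob = sc_len)
      p <- sample.int(sc_len[sc] - 100L, 1) + 50L
      gsel <- genes$scaffold == sc_names[sc]
      if (any(gsel & genes$start - 100L <= p & genes$end + 100L >= p)) next
      if (any(abs(used_pts[[sc]] - p) < 2L)) next
      pts <- rbind(pts, data.frame(
        idx = i, scaffold = sc_names[sc], point = p,
        host_gene = NA_character_, host_feature = NA_character_,
        stringsAsFactors = FALSE))
      used_pts[[sc]] <- c(used_pts[[sc]], p)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("placement error: could not find an intergenic insertion point; ",
           "genome too small or too gene-dense")
    }
  }

  # --- assemble final scaffolds, shifting coordinates ----------------------
  ledger <- vector("list", n_ins)
  final_seq <- character(nsc)
  exons$final_start <- exons$start
  exons$final_end <- exons$end
  genes$final_start <- genes$start
  genes$final_end <- genes$end
  for (sc in seq_len(nsc)) {
    bg <- .random_dna(sc_len[sc], config$gc_content)
    psc <- pts[pts$scaffold == sc_names[sc], , drop = FALSE]
    psc <- psc[order(psc$point), , drop = FALSE]
    pieces <- character(0)
    cursor <- 1L
    shift <- 0L
    for (r in seq_len(nrow(psc))) {
      i <- psc$idx[r]
      p <- psc$point[r]
      oriented <- if (ins[[i]]$strand == "+") ins[[i]]$seq_plus else {
        .revcomp(ins[[i]]$seq_plus)
      }
      itp <- interruption[[i]]
      itp_start <- itp_end <- NA_integer_
      if (is.null(itp)) {
        block <- oriented
      } else {
        half <- floor(nchar(oriented) * runif(1, 0.3, 0.7))
        block <- paste0(substr(oriented, 1L, half), itp$elem,
                        substr(oriented, half + 1L, nchar(oriented)))
        itp_start <- p + shift + half + 1L
        itp_end <- itp_start + nchar(itp$elem) - 1L
      }
      pieces <- c(pieces, substr(bg, cursor, p), block)
      nstart <- p + shift + 1L
      nend <- p + shift + nchar(block)
      ledger[[i]] <- data.frame(
        id = sprintf("numt%03d", i), nuclear_scaffold = sc_names[sc],
        nuclear_start = nstart, nuclear_end = nend,
        mito_chromosome = ins[[i]]$mito_chromosome,
        mito_start = ins[[i]]$mito_start, mito_end = ins[[i]]$mito_end,
        mito_wraps_origin = ins[[i]]$wraps_origin,
        strand = ins[[i]]$strand, divergence = ins[[i]]$divergence,
        n_subst = ins[[i]]$n_subst, length = nchar(block),
        family_id = fam_id[i],
        interrupted_kind = if (is.null(itp)) NA_character_ else itp$kind,
        interruption_start = itp_start, interruption_end = itp_end,
        host_gene = psc$host_gene[r], host_feature = psc$host_feature[r],
        est_ids = "", stringsAsFactors = FALSE)
      cursor <- p + 1L
      shift <- shift + nchar(block)
    }
    pieces <- c(pieces, substr(bg, cursor, sc_len[sc]))
    final_seq[sc] <- paste(pieces, collapse = "")
    # shift gene/exon coordinates past insertion points
    if (nrow(psc)) {
      shifts <- cumsum(vapply(seq_len(nrow(psc)), function(r) {
        i <- psc$idx[r]
        itp <- interruption[[i]]
        nchar(ins[[i]]$seq) + if (is.null(itp)) 0L else nchar(itp$elem)
      }, 0))
      shift_at <- function(x) {
        ix <- findInterval(x - 0.5, psc$point)
        x + ifelse(ix > 0, shifts[pmax(ix, 1)], 0L)
      }
      selg <- genes$scaffold == sc_names[sc]
      genes$final_start[selg] <- shift_at(genes$start[selg])
      genes$final_end[selg] <- shift_at(genes$end[selg])
      sele <- exons$scaffold == sc_names[sc]
      exons$final_start[sele] <- shift_at(exons$start[sele])
      exons$final_end[sele] <- shift_at(exons$end[sele])
    }
  }
  # gene spans must cover any intronic insertion growth
  ledger <- do.call(rbind, ledger)
  rownames(ledger) <- NULL

  names(final_seq) <- sc_names
  structure(
    list(nuclear = Biostrings::DNAStringSet(final_seq),
         genes = genes[, c("gene_id", "scaffold", "strand",
                           "final_start", "final_end", "n_exons")],
         exons = exons[, c("gene_id", "scaffold", "strand", "exon_rank",
                           "final_start", "final_end")],
         ledger = ledger, repeat_library = te_lib, config = config),
    class = "synthetic_genome")
}

# intron rank in transcription order for the intron after exon row `k`
# (exons sorted by genomic start)
.intron_rank <- function(ex_sorted, k) {
  if (ex_sorted$strand[1] == "+") k else nrow(ex_sorted) - k
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %d scaffold(s), %d bp, %d genes, %d planted NUMTs\n",
              length(x$nuclear), sum(Biostrings::width(x$nuclear)),
              nrow(x$genes), nrow(x$ledger)))
  invisible(x)
}

#' Generate simulated ESTs (pure mitochondrial, chimeric, plain nuclear)
#'
#' Produces the transcript classes the expression screen must separate:
#' `pure_mito` ESTs are mutated mitochondrial substrings (contaminants),
#' `chimeric_utr5` ESTs run from a planted upstream NUMT through the first
#' exon of the host gene (NUMT in the 5' UTR), `chimeric_internal` ESTs
#' embed a NUMT between nuclear flanks, and `plain_nuclear` ESTs carry no
#' mitochondrial homology. Composition of every EST is recorded in the
#' truth table and the ledger's `est_ids` are updated.
#'
#' @param config a [sim_config()] object.
#' @param genome a [generate_nuclear_genome()] result.
#' @param mito the matching [generate_mito_genome()] result.
#' @return list with `ests` (`DNAStringSet`), `truth` (`data.frame`:
#'   est_id, class, insertion_id, mito_chromosome, host_gene), and an
#'   updated `genome` (ledger `est_ids` filled).
#' @export
generate_ests <- function(config, genome, mito) {
  stopifnot(is(config, "sim_config"), is(genome, "synthetic_genome"),
            is(mito, "MitoGenome"))
  set.seed(.substream(config$seed, 3L))
  spec <- config$est_spec
  err <- config$est_error_rate
  led <- genome$ledger
  seqs <- character(0)
  truth <- list()
  eid <- 0L
  nm <- function() sprintf("est%03d", eid)

  add <- function(seq, class, insertion_id = NA, mito_chrom = NA,
                  host = NA) {
    eid <<- eid + 1L
    seqs[nm()] <<- .mutate_seq(seq, err, 0)$seq
    truth[[length(truth) + 1L]] <<- data.frame(
      est_id = nm(), class = class, insertion_id = insertion_id,
      mito_chromosome = mito_chrom, host_gene = host,
      stringsAsFactors = FALSE)
    nm()
  }

  for (i in seq_len(spec[["pure_mito"]])) {
    ci <- sample(length(mito$seq), 1)
    L <- Biostrings::width(mito$seq)[ci]
    len <- sample(300:min(900, L - 1), 1)
    st <- sample.int(L - len + 1L, 1)
    s <- as.character(Biostrings::subseq(mito$seq[[ci]], st, st + len - 1L))
    if (runif(1) < 0.5) s <- .revcomp(s)
    add(s, "pure_mito", mito_chrom = names(mito$seq)[ci])
  }

  if (spec[["chimeric_utr5"]] > 0) {
    cand <- which(led$host_feature == "utr5")
    if (length(cand) < spec[["chimeric_utr5"]]) {
      stop("generation error: chimeric 5'-UTR ESTs requested but the ",
           "genome has too few upstream insertions ",
           "(set est_spec before generate_nuclear_genome)")
    }
    for (i in seq_len(spec[["chimeric_utr5"]])) {
      row <- led[cand[i], ]
      ex <- genome$exons[genome$exons$gene_id == row$host_gene, ]
      first_ex <- ex[ex$exon_rank == 1L, ]
      scseq <- genome$nuclear[[row$nuclear_scaffold]]
      if (first_ex$strand == "+") {
        s <- as.character(Biostrings::subseq(
          scseq, row$nuclear_start, first_ex$final_end))
      } else {
        s <- .revcomp(as.character(Biostrings::subseq(
          scseq, first_ex$final_start, row$nuclear_end)))
      }
      id <- add(s, "chimeric_utr5", insertion_id = row$id,
                mito_chrom = row$mito_chromosome, host = row$host_gene)
      led$est_ids[cand[i]] <- paste0(led$est_ids[cand[i]], id)
    }
  }

  if (spec[["chimeric_internal"]] > 0) {
    cand <- which(is.na(led$host_feature) & is.na(led$interrupted_kind))
    if (!length(cand)) {
      stop("generation error: chimeric internal ESTs requested but no ",
           "plain insertion is available")
    }
    cand <- rep_len(cand, spec[["chimeric_internal"]])
    for (i in seq_len(spec[["chimeric_internal"]])) {
      row <- led[cand[i], ]
      scseq <- genome$nuclear[[row$nuclear_scaffold]]
      fl <- sample(100:300, 2, replace = TRUE)
      st <- max(1L, row$nuclear_start - fl[1])
      en <- min(length(scseq), row$nuclear_end + fl[2])
      s <- as.character(Biostrings::subseq(scseq, st, en))
      id <- add(s, "chimeric_internal", insertion_id = row$id,
                mito_chrom = row$mito_chromosome)
      led$est_ids[cand[i]] <- paste0(led$est_ids[cand[i]],
                                     if (nzchar(led$est_ids[cand[i]])) ",",
                                     id)
    }
  }

  if (spec[["plain_nuclear"]] > 0) {
    for (i in seq_len(spec[["plain_nuclear"]])) {
      for (att in 1:200) {
        sc <- sample(length(genome$nuclear), 1)
        L <- Biostrings::width(genome$nuclear)[sc]
        len <- sample(300:900, 1)
        st <- sample.int(L - len, 1)
        lsel <- led$nuclear_scaffold == names(genome$nuclear)[sc]
        if (!any(lsel & led$nuclear_start <= st + len - 1L &
                   led$nuclear_end >= st)) {
          s <- as.character(Biostrings::subseq(genome$nuclear[[sc]], st,
                                               st + len - 1L))
          add(s, "plain_nuclear")
          break
        }
      }
    }
  }

  genome$ledger <- led
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    est_id = character(), class = character(), insertion_id = character(),
    mito_chromosome = character(), host_gene = character(),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  ests <- if (length(seqs)) Biostrings::DNAStringSet(seqs) else {
    Biostrings::DNAStringSet()
  }
  list(ests = ests, truth = truth, genome = genome)
}
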