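# Aggregation of all stages into paper-style tables and the end-to-end
# pipeline driver.

#' Length histogram of NUMT calls
#'
#' Counts NUMT lengths in fixed-width bins `[0,100), [100,200), ...`.
#'
#' @param numts NUMT calls.
#' @param bin_bp bin width (default 100).
#' @return `data.frame`: bin_start, bin_end, count.
#' @export
numt_length_histogram <- function(numts, bin_bp = 100L) {
  if (nrow(numts) == 0) {
    return(data.frame(bin_start = integer(), bin_end = integer(),
                      count = integer()))
  }
  b <- (numts$length %/% bin_bp) * bin_bp
  tb <- table(b)
  data.frame(bin_start = as.integer(names(tb)),
             bin_end = as.integer(names(tb)) + bin_bp,
             count = as.integer(tb))
}

#' Assemble the report bundle from stage outputs
#'
#' Aggregates the stage outputs into one structure mirroring the standard
#' summary tables: the genome-summary row (counts, total/union bp,
#' cumulative percentage, mtDNA fraction transferred), per-mito-chromosome
#' counts, the length histogram, the genic-context breakdown (density
#' categories with both the all-NUMT and the non-high-density denominators),
#' duplication families, split pairs, and the expression section. Every
#' number is recomputed from the stage outputs passed in.
#'
#' @param summary a [summarize_numts()] result.
#' @param numts NUMT calls.
#' @param context optional [classify_context()] result.
#' @param duplication optional [group_duplicates()] result.
#' @param split_pairs optional classified split pairs.
#' @param expression optional [expression_screen()] result.
#' @param mode provenance flag (`per_hit` / `merged`).
#' @return object of class `numt_report` (a nested list, JSON-serializable
#'   via [write_report_json()]).
#' @export
build_report <- function(summary, numts, context = NULL, duplication = NULL,
                         split_pairs = NULL, expression = NULL,
                         mode = "per_hit") {
  stopifnot(is(summary, "NumtSummary"))
  rep <- list(
    provenance = list(mode = mode, n_numts = summary$n_numts),
    genome_summary = unclass(summary),
    per_chromosome = if (nrow(numts)) {
      tb <- table(numts$mito_chromosome)
      data.frame(mito_chromosome = names(tb), n_numts = as.integer(tb),
                 total_bp = as.integer(tapply(numts$length,
                                              numts$mito_chromosome, sum)[names(tb)]),
                 stringsAsFactors = FALSE)
    } else NULL,
    length_histogram = numt_length_histogram(numts))
  if (!is.null(context) && nrow(context)) {
    tb <- table(factor(context$density,
                       c("non_genic", "low_density", "high_density")))
    n <- sum(tb)
    n_lowish <- tb[["non_genic"]] + tb[["low_density"]]
    rep$genic_context <- list(
      counts = as.list(tb),
      percent_of_all = as.list(round(100 * tb / n, 2)),
      percent_non_high = round(100 * n_lowish / n, 2),
      intronic = sum(grepl("^intron_", context$feature)),
      exonic = sum(context$feature == "exon"),
      host_genes = context[!is.na(context$host_gene) &
                             context$feature != "intergenic",
                           c("numt_id", "host_gene", "feature",
                             "same_orientation_as_host")])
  }
  if (!is.null(duplication)) {
    rep$duplication <- list(
      n_families = nrow(duplication$families),
      family_size_histogram = if (nrow(duplication$families)) {
        tb <- table(duplication$families$family_size)
        data.frame(family_size = as.integer(names(tb)),
                   n_families = as.integer(tb))
      } else NULL,
      families = duplication$families)
  }
  if (!is.null(split_pairs)) rep$split_pairs <- split_pairs
  if (!is.null(expression)) {
    rep$expression <- list(
      n_pure_mito = length(expression$screen$pure_mito),
      n_chimeric = length(expression$screen$chimeric),
      n_no_mt = length(expression$screen$no_mt),
      report = expression$report)
  }
  class(rep) <- "numt_report"
  rep
}

#' @export
print.numt_report <- function(x, ...) {
  gs <- x$genome_summary
  cat("NUMT report (", x$provenance$mode, " mode)\n", sep = "")
  cat(sprintf("  %d NUMTs, %.0f bp (%.4f%% of genome), mtDNA transferred %.2f%%\n",
              gs$n_numts, gs$total_bp, gs$cumulative_percent,
              gs$mt_fraction_transferred))
  if (!is.null(x$genic_context)) {
    cat(sprintf("  context: %s\n",
                paste(names(x$genic_context$counts),
                      unlist(x$genic_context$counts), collapse = ", ")))
  }
  if (!is.null(x$duplication)) {
    cat(sprintf("  duplication families: %d\n", x$duplication$n_families))
  }
  if (!is.null(x$expression)) {
    cat(sprintf("  ESTs: %d pure mito, %d chimeric, %d without mtDNA\n",
                x$expression$n_pure_mito, x$expression$n_chimeric,
                x$expression$n_no_mt))
  }
  invisible(x)
}

#' Serialize a report bundle to JSON
#' @param report a [build_report()] bundle.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE, na = "null",
                       digits = NA)
  invisible(path)
}

#' Run the full pipeline on a synthetic genome
#'
#' simulate -> search -> filter -> call -> duplication/split-pair analysis
#' -> genic context -> expression screen -> report. Deterministic given the
#' config seed.
#'
#' @param config a [sim_config()].
#' @param params a [scoring_params()].
#' @param mode NUMT calling mode (`per_hit` or `merged`).
#' @return list with all stage outputs (`mito`, `genome`, `ests`, `hits`,
#'   `numts`, `summary`, `duplication`, `split_pairs`, `context`,
#'   `expression`, `report`).
#' @export
run_pipeline <- function(config = sim_config(), params = scoring_params(),
                         mode = c("per_hit", "merged")) {
  mode <- match.arg(mode)
  mito <- generate_mito_genome(config)
  genome <- generate_nuclear_genome(config, mito)
  est <- if (sum(config$est_spec) > 0) {
    generate_ests(config, genome, mito)
  } else NULL
  if (!is.null(est)) genome <- est$genome
  hits <- search_hits(mito, genome$nuclear, params = params)
  fhits <- filter_hits(hits, params$evalue_max, params$min_hit_length)
  numts <- call_numts(fhits, mode = mode)
  summ <- summarize_numts(numts, sum(Biostrings::width(genome$nuclear)),
                          mito)
  dup <- group_duplicates(numts)
  sp <- find_split_pairs(numts)
  sp <- classify_split_pairs(sp, genome$nuclear, genome$repeat_library)
  ctx <- classify_context(numts, genome)
  expr <- if (!is.null(est) && length(est$ests)) {
    expression_screen(est$ests, mito, genome, numts, annotation = genome,
                      params = params)
  } else NULL
  rep <- build_report(summ, numts, context = ctx, duplication = dup,
                      split_pairs = sp, expression = expr, mode = mode)
  list(mito = mito, genome = genome, ests = est, hits = hits,
       numts = numts, summary = summ, duplication = dup, split_pairs = sp,
       context = ctx, expression = expr, report = rep)
}
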