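# Reading corpora, writing record tables, and pipeline orchestration.

#' Read a corpus of documents
#'
#' Two plain-text input layouts are supported:
#'
#' * a tab-delimited file with header columns `doc_id`, `year`, `section`,
#'   `text` (one document per line); malformed lines (wrong field count,
#'   empty text) are skipped and counted with a warning;
#' * any other text file, read as a single document whose `doc_id` is the
#'   file name.
#'
#' @param path Path to the input file.
#' @return A tibble of documents: `doc_id`, `year`, `section`, `text`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot read corpus: no such file: ", path))
  }
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 1 && grepl("^doc_id\t", first)) {
    lines <- readr::read_lines(path, skip = 1)
    lines <- lines[nzchar(lines)]
    parts <- stringr::str_split_fixed(lines, "\t", 4)
    ok <- nzchar(parts[, 1]) & nzchar(parts[, 4])
    if (any(!ok)) {
      warn(paste0(sum(!ok), " malformed line(s) skipped in ", path))
    }
    parts <- parts[ok, , drop = FALSE]
    return(tibble(doc_id = parts[, 1],
                  year = suppressWarnings(as.integer(parts[, 2])),
                  section = ifelse(nzchar(parts[, 3]), parts[, 3], "abstract"),
                  text = parts[, 4]))
  }
  txt <- paste(readr::read_lines(path), collapse = "\n")
  tibble(doc_id = basename(path), year = NA_integer_,
         section = "abstract", text = txt)
}

#' Write a corpus of documents
#'
#' Writes the tab-delimited one-document-per-line layout read back by
#' [read_corpus()]. Embedded tabs and newlines in the text are replaced by
#' spaces.
#'
#' @param docs A tibble with columns `doc_id`, `year`, `section`, `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(docs, path) {
  stopifnot(is.data.frame(docs),
            all(c("doc_id", "year", "section", "text") %in% names(docs)))
  text <- stringr::str_replace_all(docs$text, "[\t\n\r]", " ")
  lines <- paste(docs$doc_id,
                 ifelse(is.na(docs$year), "", docs$year),
                 docs$section, text, sep = "\t")
  readr::write_lines(c("doc_id\tyear\tsection\ttext", lines), path)
  invisible(path)
}

# provenance header written at the top of every output table
.provenance_header <- function(seed = NULL, extra = character()) {
  c(paste0("# justsig version ", as.character(utils::packageVersion("justsig"))),
    if (!is.null(seed)) paste0("# seed: ", seed),
    extra,
    paste0("# written: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")))
}

#' Write a record table as CSV with a provenance header
#'
#' @param records A tibble of interval records.
#' @param path Output path.
#' @param seed Optional seed to record in the header.
#' @param extra Extra header comment lines (each prefixed `"# "`).
#' @return `path`, invisibly.
#' @export
write_record_table <- function(records, path, seed = NULL,
                               extra = character()) {
  hdr <- .provenance_header(seed, if (length(extra)) paste0("# ", extra))
  readr::write_lines(hdr, path)
  readr::write_csv(records, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a record table written by [write_record_table()]
#'
#' @param path Path to the CSV file.
#' @return A tibble of interval records.
#' @export
read_record_table <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Extract interval records from a corpus file
#'
#' Reads a corpus, runs the parser over every document and writes the
#' record table as CSV. A summary (documents read, records extracted,
#' records per document) is reported via `message()`; zero extractions is a
#' success with a warning, an unreadable input an error.
#'
#' @param corpus_path Input corpus file (see [read_corpus()]).
#' @param out_path Output CSV path; `NULL` skips writing.
#' @param grammar A [grammar_config()].
#' @return The record tibble, invisibly.
#' @export
run_extract <- function(corpus_path, out_path = NULL,
                        grammar = grammar_config()) {
  docs <- read_corpus(corpus_path)
  records <- parse_documents(docs, grammar = grammar)
  message(sprintf("read %d document(s); extracted %d record(s) (%.2f per document)",
                  nrow(docs), nrow(records),
                  if (nrow(docs) > 0) nrow(records) / nrow(docs) else 0))
  if (nrow(records) == 0) warn("no interval records extracted")
  if (!is.null(out_path)) {
    write_record_table(records, out_path,
                       extra = paste0("source: ", corpus_path))
  }
  invisible(records)
}

#' Run QC on a record table file
#'
#' Reads a record CSV, applies [apply_qc()], writes the retained records and
#' a per-rule summary table, and reports the exclusion percentages in the
#' style of a methods paragraph.
#'
#' @param records_path Input record CSV.
#' @param out_path Output CSV for retained records; `NULL` skips writing.
#' @param summary_path Output CSV for the per-rule summary; `NULL` skips.
#' @return The `qc_report`, invisibly.
#' @export
run_qc <- function(records_path, out_path = NULL, summary_path = NULL) {
  records <- read_record_table(records_path)
  report <- apply_qc(records)
  smry <- tidy(report)
  for (i in seq_len(nrow(smry))) {
    if (smry$n[i] > 0) {
      message(sprintf("excluded %.2f%% of records (%d): %s",
                      100 * smry$proportion[i], smry$n[i], smry$reason[i]))
    }
  }
  if (!is.null(out_path)) write_record_table(report$retained, out_path)
  if (!is.null(summary_path)) {
    readr::write_lines(.provenance_header(), summary_path)
    readr::write_csv(smry, summary_path, append = TRUE, col_names = TRUE)
  }
  invisible(report)
}

#' Run the full demonstration pipeline
#'
#' Simulates an unbiased and a distorted literature from one configuration,
#' renders both as text, extracts and QC-filters the rendered documents, and
#' computes the distribution diagnostics, writing all tables and figures
#' under `out_dir`. The returned report carries the headline quantities: the
#' share of significant intervals and the lower/upper-limit jump excesses in
#' both arms, plus the number of records lost between simulation and
#' extraction (zero when extraction is working).
#'
#' @param config A [sim_config()]; its `p_hack_looks` and
#'   `pub_bias_retention` define the biased arm, the unbiased arm forces
#'   them off.
#' @param out_dir Output directory, created if needed.
#' @param epsilon Jump-statistic window half-width (default 0.05).
#' @param write_figures Write ECDF figures (PDF) for both arms
#'   (default TRUE).
#' @return A list of class `end2end_report`: `unbiased` and `biased`, each
#'   with `n_simulated`, `n_published`, `n_extracted`, `n_retained`,
#'   `lost_records`, `prop_significant`, `jump_lower`, `jump_upper`; plus
#'   `config` and `out_dir`.
#' @export
run_end2end <- function(config = sim_config(), out_dir = tempdir(),
                        epsilon = 0.05, write_figures = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% NA
  arms <- list(
    unbiased = generate_unbiased_corpus(config),
    biased = generate_biased_corpus(config))
  report <- list(config = config, out_dir = out_dir)
  for (arm in names(arms)) {
    corpus <- arms[[arm]]
    rendered <- render_corpus(
      corpus, seed = if (!is.null(config$seed)) config$seed + 1L else NULL)
    write_corpus(rendered$documents, file.path(out_dir, paste0(arm, "_corpus.tsv")))
    records <- parse_documents(rendered$documents)
    write_record_table(records, file.path(out_dir, paste0(arm, "_records.csv")),
                       seed = config$seed)
    qc <- apply_qc(records)
    write_record_table(qc$retained,
                       file.path(out_dir, paste0(arm, "_retained.csv")),
                       seed = config$seed)
    readr::write_csv(tidy(qc), file.path(out_dir, paste0(arm, "_qc_summary.csv")))
    retained <- classify_significance(qc$retained)
    jl <- jump_statistic(retained$lower, "lower_limits", epsilon = epsilon)
    ju <- jump_statistic(retained$upper, "upper_limits", epsilon = epsilon)
    readr::write_csv(bind_rows(jl, ju),
                     file.path(out_dir, paste0(arm, "_jump.csv")))
    curves <- limit_ecdf_curves(retained)
    readr::write_csv(curves, file.path(out_dir, paste0(arm, "_ecdf.csv")))
    if (write_figures) {
      plot_curves(retained,
                  file = file.path(out_dir, paste0(arm, "_ecdf.pdf")))
    }
    report[[arm]] <- list(
      n_simulated = config$n_studies,
      n_published = nrow(corpus$records),
      n_extracted = nrow(records),
      n_retained = nrow(qc$retained),
      lost_records = nrow(corpus$records) - nrow(qc$retained),
      prop_significant = mean(retained$significance != "nonsig"),
      jump_lower = jl$excess,
      jump_upper = ju$excess)
    message(sprintf(
      "%s arm: %d published, %d extracted, %d retained; significant %.3f; jump excess lower %.4f upper %.4f",
      arm, nrow(corpus$records), nrow(records), nrow(qc$retained),
      report[[arm]]$prop_significant, jl$excess, ju$excess))
  }
  if (report$unbiased$lost_records != 0 || report$biased$lost_records != 0) {
    warn("records were lost between simulation and extraction")
  }
  structure(report, class = "end2end_report")
}

#' @export
print.end2end_report <- function(x, ...) {
  cat("<end2end_report> written to ", x$out_dir, "\n", sep = "")
  for (arm in c("unbiased", "biased")) {
    a <- x[[arm]]
    cat(sprintf("  %-8s published %d, retained %d, significant %.3f, jump lower %+.4f upper %+.4f\n",
                arm, a$n_published, a$n_retained, a$prop_significant,
                a$jump_lower, a$jump_upper))
  }
  invisible(x)
}
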