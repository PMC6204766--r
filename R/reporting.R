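#' Write enrichment result tables
#'
#' One table per hypothesis family (`marks_promoter`, `marks_coding`,
#' `regulators`). The TSV is a display artifact: p-values in scientific
#' notation with 3 significant figures, ratios as percentages with 2 decimal
#' places, fold enrichment with 2 decimals. The JSON mirrors every column at
#' full double precision and can be read back with [read_report_json()].
#' Rows are ordered by selected-tail raw p-value, then label, so identical
#' inputs produce byte-identical files.
#'
#' @param results an `enrichment_results` data.frame from [analyze()].
#' @param path output directory (created if needed).
#' @param formats subset of `c("tsv", "json")`.
#' @param all_rows write every tested hypothesis (`TRUE`, the "no p-value
#'   cutoff" view) or only significant ones (`FALSE`).
#' @return Invisibly, a character vector of the files written.
#' @export
write_report <- function(results, path, formats = c("tsv", "json"),
                         all_rows = TRUE) {
  stopifnot(inherits(results, "enrichment_results"))
  formats <- match.arg(formats, c("tsv", "json"), several.ok = TRUE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (fam in c("marks_promoter", "marks_coding", "regulators")) {
    rows <- results[results$family == fam, , drop = FALSE]
    if (!all_rows) rows <- rows[rows$significant, , drop = FALSE]
    rows <- rows[order(rows$p_raw, rows$label,
                       method = "radix", na.last = TRUE), , drop = FALSE]
    if ("tsv" %in% formats) {
      f <- file.path(path, paste0(fam, ".tsv"))
      utils::write.table(report_display(rows), f, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
      written <- c(written, f)
    }
    if ("json" %in% formats) {
      f <- file.path(path, paste0(fam, ".json"))
      cols <- c("label", "region", "condition", "family", "trend",
                "p_raw", "p_corrected",
                "p_enrich_raw", "p_deplete_raw",
                "p_enrich_corrected", "p_deplete_corrected",
                "fold_enrichment", "observed_ratio", "expected_ratio",
                "T", "R", "S", "F", "untestable", "significant")
      jsonlite::write_json(rows[cols], f, dataframe = "rows",
                           auto_unbox = TRUE, digits = I(17), na = "null",
                           pretty = TRUE)
      written <- c(written, f)
    }
  }
  invisible(written)
}

report_display <- function(rows) {
  data.frame(
    label = rows$label,
    region = rows$region,
    condition = ifelse(is.na(rows$condition), "", rows$condition),
    trend = rows$trend,
    p_raw = format_pvalue(rows$p_raw),
    p_corrected = format_pvalue(rows$p_corrected),
    fold_enrichment = format_fold(rows$fold_enrichment),
    observed_ratio = format_percent(rows$observed_ratio),
    expected_ratio = format_percent(rows$expected_ratio),
    T = rows$T, R = rows$R, S = rows$S, F = rows$F,
    stringsAsFactors = FALSE, check.names = FALSE
  )
}

#' Read back a JSON result table written by [write_report()]
#'
#' @param path a `<family>.json` file.
#' @return A data.frame with the full-precision columns.
#' @export
read_report_json <- function(path) {
  jsonlite::fromJSON(path)
}

#' Volcano-plot data
#'
#' One point per tested hypothesis: x = fold enrichment, y = -log10 of the
#' selected-tail raw p-value. Rows with p exactly 0 (underflow) get y capped
#' at 320 — just above the double-precision -log10 range — and are flagged.
#'
#' @param results an `enrichment_results` data.frame.
#' @param cap y value substituted for p = 0 rows.
#' @return data.frame with `label`, `region`, `condition`, `x`, `y`, `trend`,
#'   `capped`.
#' @export
volcano_data <- function(results, cap = 320) {
  stopifnot(inherits(results, "enrichment_results"))
  p <- results$p_raw
  capped <- !is.na(p) & p == 0
  y <- ifelse(capped, cap, -log10(p))
  data.frame(
    label = results$label, region = results$region,
    condition = results$condition,
    x = results$fold_enrichment, y = y,
    trend = results$trend, capped = capped,
    stringsAsFactors = FALSE
  )
}

#' Bar-chart data, sorted by fold enrichment and by p-value
#'
#' @param results an `enrichment_results` data.frame.
#' @return A list of two data.frames: `by_fold` (fold non-increasing) and
#'   `by_p` (selected-tail raw p non-decreasing).
#' @export
bar_data <- function(results) {
  stopifnot(inherits(results, "enrichment_results"))
  base <- data.frame(
    label = results$label, region = results$region,
    condition = results$condition,
    fold_enrichment = results$fold_enrichment, p_raw = results$p_raw,
    trend = results$trend, stringsAsFactors = FALSE
  )
  list(
    by_fold = base[order(-base$fold_enrichment, base$label,
                         method = "radix", na.last = TRUE), , drop = FALSE],
    by_p = base[order(base$p_raw, base$label,
                      method = "radix", na.last = TRUE), , drop = FALSE]
  )
}

#' Command-line driver
#'
#' Runs the full pipeline: resolve the gene list, score each signal track
#' over promoters and coding regions, build mark sets at the requested
#' thresholds, load regulator target sets, test enrichment/depletion, and
#' write the report bundle. Intended to be called from the thin wrapper
#' script shipped in `inst/scripts/yeastmarks.R`.
#'
#' Flags: `--genes FILE`, `--annotation FILE`,
#' `--annotation-format {tsv,gff3}`, `--marks MANIFEST`,
#' `--regulators FILE`, `--regulators-format {gmt,tsv}`,
#' `--threshold NAME=VALUE` (repeatable; `--threshold VALUE` sets the
#' default for unnamed datasets), `--correction {bonferroni,fdr,none}`,
#' `--alpha FLOAT` (default 0.01), `--no-cutoff`, `--out DIR`,
#' `--export-sets`, `--seed INT`, `--log-level {info,quiet}`.
#'
#' The marks manifest is a TSV with header
#' `name, file, format, value_kind, condition`; file paths are resolved
#' relative to the manifest. `--no-cutoff` writes every hypothesis (trend
#' still labelled at the default 0.01) and conflicts with `--alpha`.
#' A machine-readable `settings.json` echo and `unresolved_names.txt` are
#' always written. Logging goes to stderr; results go to files only.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit code: 0 on success, 2 on validation errors.
#' @export
run_cli <- function(args) {
  code <- tryCatch({
    opts <- parse_cli_args(args)
    run_pipeline(opts)
    0L
  }, cli_error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  code
}

cli_error <- function(...) {
  stop(structure(class = c("cli_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

parse_cli_args <- function(args) {
  opts <- list(thresholds = c(), default_threshold = 1,
               correction = "bonferroni", alpha = NULL, no_cutoff = FALSE,
               annotation_format = "tsv", regulators_format = "gmt",
               export_sets = FALSE, seed = NULL, log_level = "info")
  i <- 1L
  take <- function() {
    if (i + 1L > length(args)) cli_error("missing value for ", args[i])
    args[i + 1L]
  }
  while (i <= length(args)) {
    a <- args[i]
    adv <- 2L
    switch(a,
      "--genes" = opts$genes <- take(),
      "--annotation" = opts$annotation <- take(),
      "--annotation-format" = opts$annotation_format <- take(),
      "--marks" = opts$marks <- take(),
      "--regulators" = opts$regulators <- take(),
      "--regulators-format" = opts$regulators_format <- take(),
      "--correction" = opts$correction <- take(),
      "--alpha" = opts$alpha <- suppressWarnings(as.numeric(take())),
      "--out" = opts$out <- take(),
      "--seed" = opts$seed <- suppressWarnings(as.integer(take())),
      "--log-level" = opts$log_level <- take(),
      "--threshold" = {
        v <- take()
        if (grepl("=", v, fixed = TRUE)) {
          kv <- strsplit(v, "=", fixed = TRUE)[[1L]]
          num <- suppressWarnings(as.numeric(kv[2L]))
          if (is.na(num)) cli_error("bad --threshold value: ", v)
          opts$thresholds[kv[1L]] <- num
        } else {
          num <- suppressWarnings(as.numeric(v))
          if (is.na(num)) cli_error("bad --threshold value: ", v)
          opts$default_threshold <- num
        }
      },
      "--no-cutoff" = { opts$no_cutoff <- TRUE; adv <- 1L },
      "--export-sets" = { opts$export_sets <- TRUE; adv <- 1L },
      cli_error("unknown flag: ", a)
    )
    i <- i + adv
  }
  if (is.null(opts$genes)) cli_error("--genes is required")
  if (is.null(opts$annotation)) cli_error("--annotation is required")
  if (is.null(opts$marks)) cli_error("--marks is required")
  if (is.null(opts$out)) cli_error("--out is required")
  if (opts$no_cutoff && !is.null(opts$alpha)) {
    cli_error("--alpha conflicts with --no-cutoff")
  }
  if (!is.null(opts$alpha) && (is.na(opts$alpha) ||
                               opts$alpha <= 0 || opts$alpha > 1)) {
    cli_error("--alpha must lie in (0, 1]")
  }
  if (!opts$correction %in% c("bonferroni", "fdr", "none")) {
    cli_error("--correction must be bonferroni, fdr or none")
  }
  if (!opts$annotation_format %in% c("tsv", "gff3")) {
    cli_error("--annotation-format must be tsv or gff3")
  }
  opts
}

cli_log <- function(opts, ...) {
  if (!identical(opts$log_level, "quiet")) message(...)
}

run_pipeline <- function(opts) {
  if (!is.null(opts$seed)) set.seed(opts$seed)
  alpha <- if (is.null(opts$alpha)) 0.01 else opts$alpha

  ann <- load_annotation(opts$annotation, opts$annotation_format)
  cli_log(opts, "annotation: ", ann$F, " genes")

  names_in <- read_gene_list(opts$genes)
  if (length(names_in) == 0L) cli_error("gene list is empty: ", opts$genes)
  res_names <- resolve_gene_names(names_in, ann)
  if (length(res_names$resolved) == 0L) {
    cli_error("no input gene names could be resolved")
  }
  cli_log(opts, "gene list: ", length(res_names$resolved), " resolved, ",
          length(res_names$unresolved), " unresolved")

  manifest <- utils::read.delim(opts$marks, stringsAsFactors = FALSE,
                                colClasses = "character")
  need <- c("name", "file", "format")
  if (!all(need %in% names(manifest))) {
    cli_error("marks manifest needs columns: ", paste(need, collapse = ", "))
  }
  if (!"value_kind" %in% names(manifest)) manifest$value_kind <- NA_character_
  if (!"condition" %in% names(manifest)) manifest$condition <- NA_character_

  mark_sets <- list()
  for (k in seq_len(nrow(manifest))) {
    m <- manifest[k, ]
    thr <- if (m$name %in% names(opts$thresholds)) {
      opts$thresholds[[m$name]]
    } else {
      opts$default_threshold
    }
    f <- m$file
    if (!file.exists(f)) f <- file.path(dirname(opts$marks), m$file)
    cond <- if (is.na(m$condition) || !nzchar(m$condition)) {
      NA_character_
    } else {
      m$condition
    }
    if (m$format == "gene_table") {
      tabs <- read_signal(f, "gene_table", name = m$name,
                          value_kind = m$value_kind, condition = cond)
      mark_sets <- c(mark_sets,
                     list(build_mark_set(tabs$promoter, thr),
                          build_mark_set(tabs$coding, thr)))
    } else {
      ds <- read_signal(f, m$format, name = m$name,
                        value_kind = m$value_kind, condition = cond)
      mark_sets <- c(mark_sets, list(
        build_mark_set(score_genes(ds, ann, "promoter"), thr),
        build_mark_set(score_genes(ds, ann, "coding"), thr)
      ))
    }
    cli_log(opts, "mark ", m$name, ": threshold ", thr)
  }

  regulator_sets <- NULL
  if (!is.null(opts$regulators)) {
    regulator_sets <- load_regulator_targets(opts$regulators,
                                             opts$regulators_format, ann)
  }

  results <- analyze(res_names$resolved, mark_sets, regulator_sets, ann,
                     correction = opts$correction, alpha = alpha)

  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  write_report(results, opts$out, all_rows = opts$no_cutoff)
  writeLines(res_names$unresolved,
             file.path(opts$out, "unresolved_names.txt"))
  utils::write.table(volcano_data(results),
                     file.path(opts$out, "volcano.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (opts$export_sets) {
    export_set_catalog(c(mark_sets, regulator_sets %||% list()),
                       file.path(opts$out, "sets"))
  }
  settings <- list(
    genes = opts$genes, annotation = opts$annotation, marks = opts$marks,
    regulators = opts$regulators,
    thresholds = as.list(opts$thresholds),
    default_threshold = opts$default_threshold,
    correction = opts$correction, alpha = alpha,
    no_cutoff = opts$no_cutoff, seed = opts$seed,
    n_input = length(res_names$resolved),
    n_unresolved = length(res_names$unresolved),
    universe_size = ann$F
  )
  jsonlite::write_json(settings, file.path(opts$out, "settings.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  cli_log(opts, "report written to ", opts$out)
  invisible(results)
}
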