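#' Gene set
#'
#' The set `S` of genes whose promoter/coding region contains a mark at a
#' threshold, or whose promoter is bound by a regulator. `provenance` records
#' the threshold used, or `"curated"` for loaded target lists.
#'
#' @param members character vector of systematic gene ids.
#' @param label mark or regulator name.
#' @param region_kind `"promoter"` or `"coding"`.
#' @param condition optional free-text tag (e.g. `"25C"`, `"37C"`, `"H2O2"`).
#' @param provenance threshold value or `"curated"`.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(members, label, region_kind = c("promoter", "coding"),
                     condition = NA_character_, provenance = "curated") {
  region_kind <- match.arg(region_kind)
  if (!nzchar(label) || is.na(label)) stop("gene set label must be nonempty")
  structure(
    list(label = label, region_kind = region_kind, condition = condition,
         members = unique(as.character(members)), provenance = provenance),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set", x$label, paste0("[", x$region_kind,
      if (!is.na(x$condition)) paste0(", ", x$condition), "]:"),
      length(x$members), "genes\n")
  invisible(x)
}

#' Build the set of genes containing a mark at a threshold
#'
#' A gene belongs to the set when its (non-missing) maximal signal value is
#' greater than or equal to the threshold; the comparison is inclusive and
#' genes with missing scores are excluded while staying in the universe.
#'
#' @param scores a [gene_score_table()].
#' @param threshold finite numeric threshold on the score (e.g. a log2
#'   IP/control ratio; 1 means 2-fold over background).
#' @return A [gene_set()] whose `provenance` records the threshold.
#' @export
build_mark_set <- function(scores, threshold) {
  stopifnot(inherits(scores, "gene_score_table"), is.finite(threshold))
  s <- scores$scores
  members <- names(s)[!is.na(s) & s >= threshold]
  gene_set(members, label = scores$dataset, region_kind = scores$region_kind,
           condition = scores$condition, provenance = threshold)
}

#' Load regulator target-gene sets
#'
#' GMT input has one set per line: `label<TAB>description<TAB>member...`;
#' labels of the form `Name_Condition` (e.g. `Esa1_25C`) are split at the
#' last underscore into regulator name and condition. TSV input has header
#' columns `regulator`, `condition`, `gene_id` and yields one set per
#' (regulator, condition) pair. All sets are promoter-binding sets.
#'
#' Members absent from the annotation are dropped with a warning; dropped
#' counts per set are attached as the `"load_report"` attribute.
#'
#' @param path file path.
#' @param format `"gmt"` or `"tsv"`.
#' @param ann optional [annotation()]; when supplied, membership is checked.
#' @return A list of [gene_set()]s with `region_kind = "promoter"`.
#' @export
load_regulator_targets <- function(path, format = c("gmt", "tsv"), ann = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("regulator file not found: ", path)
  if (format == "gmt") {
    raw <- read_gmt(path)
    sets <- lapply(raw, function(x) {
      lc <- split_label_condition(x$label)
      gene_set(x$members, label = lc$label, region_kind = "promoter",
               condition = lc$condition, provenance = "curated")
    })
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!all(c("regulator", "condition", "gene_id") %in% names(tab))) {
      stop("regulator TSV must have columns regulator, condition, gene_id")
    }
    key <- paste(tab$regulator, tab$condition, sep = "\r")
    sets <- lapply(split(seq_len(nrow(tab)), key), function(i) {
      gene_set(tab$gene_id[i], label = tab$regulator[i[1L]],
               region_kind = "promoter", condition = tab$condition[i[1L]],
               provenance = "curated")
    })
    names(sets) <- NULL
  }
  report <- stats::setNames(integer(length(sets)),
                            vapply(sets, set_display_name, ""))
  if (!is.null(ann)) {
    known <- ann$genes$gene_id
    for (i in seq_along(sets)) {
      unknown <- setdiff(sets[[i]]$members, known)
      if (length(unknown) > 0L) {
        report[i] <- length(unknown)
        sets[[i]]$members <- setdiff(sets[[i]]$members, unknown)
      }
    }
    if (sum(report) > 0L) {
      warning(sum(report), " target gene(s) absent from annotation dropped")
    }
  }
  attr(sets, "load_report") <- report
  sets
}

split_label_condition <- function(label) {
  if (grepl("_", label)) {
    pos <- max(gregexpr("_", label)[[1L]])
    list(label = substr(label, 1L, pos - 1L),
         condition = substr(label, pos + 1L, nchar(label)))
  } else {
    list(label = label, condition = NA_character_)
  }
}

set_display_name <- function(s) {
  if (is.na(s$condition)) s$label else paste(s$label, s$condition, sep = "_")
}

read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stop("malformed GMT line: ", l)
    members <- if (length(f) > 2L) f[-(1:2)] else character(0)
    list(label = f[1L], description = f[2L],
         members = members[nzchar(members)])
  })
}

#' Export a gene-set catalog
#'
#' Writes `catalog.gmt` (one line per set; label encodes the condition as
#' `Name_Condition`, the description field records region kind, condition
#' and provenance) and `members.tsv` (one row per set member). Reloading the
#' GMT with [read_set_catalog()] reproduces membership, labels, region kinds
#' and conditions exactly.
#'
#' @param sets list of [gene_set()]s.
#' @param path output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_set_catalog <- function(sets, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  gmt_path <- file.path(path, "catalog.gmt")
  members_path <- file.path(path, "members.tsv")
  lines <- vapply(sets, function(s) {
    desc <- paste0("region_kind=", s$region_kind,
                   ";condition=", ifelse(is.na(s$condition), "", s$condition),
                   ";provenance=", as.character(s$provenance))
    paste(c(set_display_name(s), desc, s$members), collapse = "\t")
  }, "")
  writeLines(lines, gmt_path)
  rows <- do.call(rbind, lapply(sets, function(s) {
    if (length(s$members) == 0L) return(NULL)
    data.frame(label = s$label, region_kind = s$region_kind,
               condition = ifelse(is.na(s$condition), "", s$condition),
               gene_id = s$members, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(label = character(0), region_kind = character(0),
                       condition = character(0), gene_id = character(0))
  }
  utils::write.table(rows, members_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(gmt = gmt_path, members = members_path))
}

#' Reload a gene-set catalog written by [export_set_catalog()]
#'
#' @param path the catalog directory or the `catalog.gmt` file itself.
#' @return A list of [gene_set()]s.
#' @export
read_set_catalog <- function(path) {
  gmt_path <- if (dir.exists(path)) file.path(path, "catalog.gmt") else path
  raw <- read_gmt(gmt_path)
  lapply(raw, function(x) {
    meta <- parse_catalog_desc(x$description)
    lc <- if (nzchar(meta[["condition"]])) {
      list(label = sub(paste0("_", meta[["condition"]], "$"), "", x$label),
           condition = meta[["condition"]])
    } else {
      list(label = x$label, condition = NA_character_)
    }
    prov <- meta[["provenance"]]
    prov_num <- suppressWarnings(as.numeric(prov))
    gene_set(x$members, label = lc$label, region_kind = meta[["region_kind"]],
             condition = lc$condition,
             provenance = if (!is.na(prov_num)) prov_num else prov)
  })
}

parse_catalog_desc <- function(desc) {
  parts <- strsplit(desc, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[2L] else "", "")
  stats::setNames(vals, vapply(kv, `[`, "", 1L))
}
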