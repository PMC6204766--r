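#' ChIP signal dataset
#'
#' A named collection of interval-valued signal (e.g. `log2(H3K4ac/H3)` probe
#' ratios or MAT scores) over a genome, stored 0-based half-open.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `value` (finite real).
#' @param name modification label, e.g. `"H3K4ac"`.
#' @param value_kind free-text semantics, e.g. `"log2(H3K4ac/H3)"`.
#' @param condition optional free-text condition tag (e.g. `"H2O2"`).
#' @return An object of class `signal_dataset`.
#' @export
signal_dataset <- function(intervals, name, value_kind = NA_character_,
                           condition = NA_character_) {
  if (!nzchar(name) || is.na(name)) stop("dataset name must be nonempty")
  intervals <- as.data.frame(intervals)[c("chrom", "start", "end", "value")]
  intervals$chrom <- as.character(intervals$chrom)
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  intervals$value <- as.numeric(intervals$value)
  if (any(intervals$end < intervals$start)) stop("negative-length interval")
  if (any(!is.finite(intervals$value))) stop("signal values must be finite")
  structure(
    list(name = name, value_kind = value_kind, condition = condition,
         intervals = intervals),
    class = "signal_dataset"
  )
}

#' @export
print.signal_dataset <- function(x, ...) {
  cat("signal_dataset", x$name, "(", x$value_kind, "):",
      nrow(x$intervals), "intervals\n")
  invisible(x)
}

#' Per-gene score table
#'
#' Holds, for one dataset and one region kind, the maximal signal value in
#' each gene's region; `NA` marks genes whose region no interval overlaps.
#'
#' @param scores named numeric vector, names are gene ids; `NA` = missing.
#' @param dataset dataset name.
#' @param region_kind `"promoter"` or `"coding"`.
#' @param condition optional condition tag carried over from the dataset.
#' @return An object of class `gene_score_table`.
#' @export
gene_score_table <- function(scores, dataset,
                             region_kind = c("promoter", "coding"),
                             condition = NA_character_) {
  region_kind <- match.arg(region_kind)
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("scores must be a named vector of gene ids")
  }
  structure(
    list(dataset = dataset, region_kind = region_kind,
         condition = condition, scores = scores),
    class = "gene_score_table"
  )
}

#' Read ChIP signal from bedGraph, wiggle or a per-gene score table
#'
#' bedGraph (natively 0-based half-open) and wiggle (1-based `fixedStep` /
#' `variableStep`, `span` honoured) are parsed with `rtracklayer::import()`
#' and stored in the internal 0-based half-open convention. A `gene_table` is
#' a TSV with header `gene_id`, `promoter_score`, `coding_score` (empty cell
#' = missing) and yields a list of two [gene_score_table()]s.
#'
#' @param path file path.
#' @param format `"bedgraph"`, `"wiggle"` or `"gene_table"`.
#' @param name dataset name; defaults to the file's base name.
#' @param value_kind,condition metadata passed to [signal_dataset()].
#' @return A [signal_dataset()] for track formats; for `gene_table`, a list
#'   with elements `promoter` and `coding`, each a [gene_score_table()].
#' @export
read_signal <- function(path, format = c("bedgraph", "wiggle", "gene_table"),
                        name = NULL, value_kind = NA_character_,
                        condition = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("signal file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (format == "gene_table") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c("character", "numeric", "numeric"))
    if (!all(c("gene_id", "promoter_score", "coding_score") %in% names(tab))) {
      stop("gene_table must have columns gene_id, promoter_score, coding_score")
    }
    return(list(
      promoter = gene_score_table(
        stats::setNames(tab$promoter_score, tab$gene_id), name,
        "promoter", condition),
      coding = gene_score_table(
        stats::setNames(tab$coding_score, tab$gene_id), name,
        "coding", condition)
    ))
  }
  fmt <- if (format == "bedgraph") "bedGraph" else "wig"
  gr <- rtracklayer::import(path, format = fmt)
  intervals <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score),
    stringsAsFactors = FALSE
  )
  signal_dataset(intervals, name = name, value_kind = value_kind,
                 condition = condition)
}

signal_granges <- function(ds) {
  iv <- ds$intervals
  nonempty <- iv$end > iv$start
  iv <- iv[nonempty, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end)
  )
  gr$value <- iv$value
  gr
}

#' Maximal signal value overlapping a region
#'
#' Overlap is any nonempty half-open intersection (at least 1 bp). Returns
#' `NA` when no interval of the dataset overlaps the region.
#'
#' @param ds a [signal_dataset()].
#' @param r a [region()].
#' @return Numeric scalar, or `NA` when the region carries no signal.
#' @export
max_signal <- function(ds, r) {
  stopifnot(inherits(ds, "signal_dataset"), inherits(r, "region"))
  if (r$end <= r$start) return(NA_real_)
  iv <- ds$intervals
  hit <- iv$chrom == r$chrom & iv$start < r$end & iv$end > r$start
  if (!any(hit)) return(NA_real_)
  max(iv$value[hit])
}

#' Score every gene of an annotation against a signal dataset
#'
#' For each gene, extracts the maximal data value over its promoter or coding
#' region — the statistic later thresholded by [build_mark_set()]. Genes
#' whose region overlaps no interval score `NA` and are treated downstream as
#' not containing the mark while remaining in the universe.
#'
#' @param ds a [signal_dataset()].
#' @param ann a [annotation()] object.
#' @param region_kind `"promoter"` or `"coding"`.
#' @return A [gene_score_table()] with one entry per annotated gene.
#' @export
score_genes <- function(ds, ann, region_kind = c("promoter", "coding")) {
  region_kind <- match.arg(region_kind)
  stopifnot(inherits(ds, "signal_dataset"), inherits(ann, "yeast_annotation"))
  regs <- gene_regions(ann, region_kind)
  scores <- stats::setNames(rep(NA_real_, nrow(regs)), regs$gene_id)
  nonempty <- regs$end > regs$start
  if (any(nonempty) && nrow(ds$intervals) > 0L) {
    q <- GenomicRanges::GRanges(
      seqnames = regs$chrom[nonempty],
      ranges = IRanges::IRanges(start = regs$start[nonempty] + 1L,
                                end = regs$end[nonempty])
    )
    subj <- signal_granges(ds)
    ov <- GenomicRanges::findOverlaps(q, subj)
    if (length(ov) > 0L) {
      mx <- tapply(subj$value[S4Vectors::subjectHits(ov)],
                   S4Vectors::queryHits(ov), max)
      idx <- which(nonempty)[as.integer(names(mx))]
      scores[idx] <- as.numeric(mx)
    }
  }
  gene_score_table(scores, dataset = ds$name, region_kind = region_kind,
                   condition = ds$condition)
}
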