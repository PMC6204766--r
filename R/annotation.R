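#' Gene annotation with codon-anchored coordinates
#'
#' An annotation holds one record per gene: a systematic name, optional
#' aliases, chromosome, strand, and the two codon anchors from which promoter
#' and coding regions are derived. All internal coordinates are 0-based
#' half-open; GFF3 input (1-based inclusive) is converted on read.
#'
#' `start_codon_pos` is the 0-based coordinate of the first base of the start
#' codon *in transcription direction*: on the `+` strand this is the leftmost
#' base of the gene, on the `-` strand the rightmost. `stop_codon_end` is the
#' 0-based exclusive coordinate one past the last base of the stop codon in
#' transcription direction, so on the `-` strand it is one base *left* of the
#' gene's leftmost base and `stop_codon_end < start_codon_pos`.
#'
#' @param genes data.frame with columns `gene_id`, `aliases` (semicolon-joined
#'   string, may be empty), `chrom`, `strand` (`+`/`-`), `start_codon_pos`,
#'   `stop_codon_end`.
#' @param chrom_lengths named integer vector of chromosome lengths in bp. If
#'   `NULL`, each chromosome's length is inferred as the smallest length that
#'   contains all of its genes.
#' @return An object of class `yeast_annotation`: a list with elements
#'   `genes` (the validated data.frame), `chrom_lengths`, and `F` (the
#'   universe size, i.e. the number of genes).
#' @export
annotation <- function(genes, chrom_lengths = NULL) {
  required <- c("gene_id", "aliases", "chrom", "strand",
                "start_codon_pos", "stop_codon_end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  genes <- as.data.frame(genes)[required]
  genes$gene_id <- as.character(genes$gene_id)
  genes$aliases <- as.character(genes$aliases)
  genes$aliases[is.na(genes$aliases)] <- ""
  genes$chrom <- as.character(genes$chrom)
  genes$strand <- as.character(genes$strand)
  genes$start_codon_pos <- as.integer(genes$start_codon_pos)
  genes$stop_codon_end <- as.integer(genes$stop_codon_end)

  if (any(!nzchar(genes$gene_id)) || anyNA(genes$gene_id)) {
    stop("gene_id must be nonempty")
  }
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0L) {
    stop("duplicate gene_id: ", paste(dup, collapse = ", "))
  }
  bad_strand <- genes$strand[!genes$strand %in% c("+", "-")]
  if (length(bad_strand) > 0L) stop("strand must be '+' or '-'")
  plus <- genes$strand == "+"
  if (any(plus & genes$start_codon_pos >= genes$stop_codon_end)) {
    stop("on the + strand start_codon_pos must be < stop_codon_end")
  }
  if (any(!plus & genes$stop_codon_end >= genes$start_codon_pos)) {
    stop("on the - strand stop-codon coordinates must precede the start codon")
  }

  # genome-ordered span of each gene (coding region, both codons included)
  span_start <- ifelse(plus, genes$start_codon_pos, genes$stop_codon_end + 1L)
  span_end <- ifelse(plus, genes$stop_codon_end, genes$start_codon_pos + 1L)
  if (any(span_start < 0L)) stop("gene coordinates must be non-negative")

  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(span_end, genes$chrom, max)
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
  } else {
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
    unknown <- setdiff(unique(genes$chrom), names(chrom_lengths))
    if (length(unknown) > 0L) {
      stop("no chromosome length for: ", paste(unknown, collapse = ", "))
    }
    too_far <- span_end > chrom_lengths[genes$chrom]
    if (any(too_far)) {
      stop("gene coordinates outside chromosome length: ",
           paste(genes$gene_id[too_far], collapse = ", "))
    }
  }

  structure(
    list(genes = genes, chrom_lengths = chrom_lengths, F = nrow(genes)),
    class = "yeast_annotation"
  )
}

#' @export
print.yeast_annotation <- function(x, ...) {
  cat("yeast_annotation:", x$F, "genes on",
      length(x$chrom_lengths), "chromosome(s)\n")
  invisible(x)
}

#' Load a gene annotation from TSV or GFF3
#'
#' The TSV dialect has a header line and columns `gene_id`, `aliases`
#' (semicolon-joined, may be empty), `chrom`, `strand`, `start_codon_pos`,
#' `stop_codon_end` (0-based, see [annotation()]). Lines starting with `#`
#' are ignored, except for optional directives
#' `#chrom_length <chrom> <length>` which declare chromosome lengths.
#'
#' GFF3 input is parsed with `rtracklayer::import()`; features of type
#' `gene` are used (all features if none is typed `gene`), 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention,
#' and chromosome lengths are taken from `##sequence-region` pragmas when
#' present.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gff3"`.
#' @param chrom_lengths optional named integer vector overriding lengths.
#' @return A [annotation()] object.
#' @export
load_annotation <- function(path, format = c("tsv", "gff3"),
                            chrom_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "tsv") {
    load_annotation_tsv(path, chrom_lengths)
  } else {
    load_annotation_gff3(path, chrom_lengths)
  }
}

load_annotation_tsv <- function(path, chrom_lengths = NULL) {
  lines <- readLines(path, warn = FALSE)
  directive <- grepl("^#chrom_length[ \t]", lines)
  if (is.null(chrom_lengths) && any(directive)) {
    parts <- strsplit(trimws(sub("^#chrom_length[ \t]+", "", lines[directive])),
                      "[ \t]+")
    chrom_lengths <- stats::setNames(
      as.integer(vapply(parts, `[`, "", 2L)),
      vapply(parts, `[`, "", 1L)
    )
  }
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(keep) < 1L) stop("annotation TSV has no data lines")
  header <- strsplit(lines[keep[1L]], "\t", fixed = TRUE)[[1L]]
  required <- c("gene_id", "aliases", "chrom", "strand",
                "start_codon_pos", "stop_codon_end")
  if (!all(required %in% header)) {
    stop("annotation TSV header must contain: ", paste(required, collapse = ", "))
  }
  rows <- lapply(keep[-1L], function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    length(fields) <- length(header)   # pad trailing empty cells
    if (sum(!is.na(fields)) < length(header) - 1L &&
        any(is.na(fields[seq_len(length(header))][header != "aliases"]))) {
      stop("malformed annotation line ", i, " in ", path)
    }
    fields
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- header
  genes <- as.data.frame(mat, stringsAsFactors = FALSE)[required]
  genes$aliases[is.na(genes$aliases)] <- ""
  n_start <- suppressWarnings(as.integer(genes$start_codon_pos))
  n_stop <- suppressWarnings(as.integer(genes$stop_codon_end))
  bad <- which(is.na(n_start) | is.na(n_stop))
  if (length(bad) > 0L) {
    stop("malformed annotation line ", keep[-1L][bad[1L]],
         " in ", path, ": non-integer coordinate")
  }
  genes$start_codon_pos <- n_start
  genes$stop_codon_end <- n_stop
  annotation(genes, chrom_lengths)
}

load_annotation_gff3 <- function(path, chrom_lengths = NULL) {
  gff <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gff$type)
  if (any(types == "gene")) gff <- gff[types == "gene"]
  ids <- gff$ID
  if (is.null(ids) || anyNA(ids)) {
    nm <- gff$Name
    if (!is.null(nm)) ids <- ifelse(is.na(ids) | !nzchar(ids), nm, ids)
  }
  if (is.null(ids)) stop("GFF3 gene features carry no ID or Name attribute")
  aliases <- character(length(gff))
  alias_col <- gff$Alias
  name_col <- gff$Name
  for (i in seq_along(gff)) {
    al <- character(0)
    if (!is.null(alias_col)) al <- c(al, unlist(alias_col[i]))
    if (!is.null(name_col) && !is.na(name_col[i]) && name_col[i] != ids[i]) {
      al <- c(al, name_col[i])
    }
    aliases[i] <- paste(unique(al[!is.na(al) & nzchar(al)]), collapse = ";")
  }
  strand <- as.character(GenomicRanges::strand(gff))
  if (any(strand == "*")) stop("GFF3 gene without strand")
  start1 <- GenomicRanges::start(gff)   # 1-based inclusive
  end1 <- GenomicRanges::end(gff)
  genes <- data.frame(
    gene_id = as.character(ids),
    aliases = aliases,
    chrom = as.character(GenomicRanges::seqnames(gff)),
    strand = strand,
    start_codon_pos = ifelse(strand == "+", start1 - 1L, end1 - 1L),
    stop_codon_end = ifelse(strand == "+", end1, start1 - 2L),
    stringsAsFactors = FALSE
  )
  if (is.null(chrom_lengths)) {
    sl <- GenomeInfoDb::seqlengths(gff)
    if (!all(is.na(sl))) {
      chrom_lengths <- sl[!is.na(sl)]
    } else {
      # rtracklayer drops ##sequence-region pragmas; read them directly
      pragmas <- grep("^##sequence-region", readLines(path, warn = FALSE),
                      value = TRUE)
      if (length(pragmas) > 0L) {
        parts <- strsplit(trimws(pragmas), "[ \t]+")
        chrom_lengths <- stats::setNames(
          as.integer(vapply(parts, `[`, "", 4L)),
          vapply(parts, `[`, "", 2L)
        )
      }
    }
  }
  annotation(genes, chrom_lengths)
}

#' Read a gene list from a plain-text file
#'
#' One name per line; blank lines and lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return Character vector of names as given (trimmed).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !grepl("^#", lines)]
}

#' Resolve user-supplied gene names against an annotation
#'
#' Matching is case-insensitive over systematic names and aliases, after
#' trimming whitespace. Duplicate inputs (including case variants) collapse
#' to a single membership. Unresolved names are returned, never silently
#' dropped; the input-list size used downstream is the number of *resolved*
#' genes.
#'
#' @param names character vector of gene names.
#' @param ann a [annotation()] object.
#' @return A list with `resolved` (character vector of systematic gene ids,
#'   in annotation order) and `unresolved` (distinct unmatched input names,
#'   first spelling seen).
#' @export
resolve_gene_names <- function(names, ann) {
  stopifnot(inherits(ann, "yeast_annotation"))
  names <- trimws(as.character(names))
  names <- names[nzchar(names)]
  if (length(names) == 0L) stop("no genes supplied")

  lut <- annotation_name_lut(ann)
  key <- tolower(names)
  first <- !duplicated(key)
  hit <- lut[key[first]]
  resolved <- unique(hit[!is.na(hit)])
  resolved <- ann$genes$gene_id[ann$genes$gene_id %in% resolved]
  unresolved <- names[first][is.na(hit)]
  list(resolved = resolved, unresolved = unresolved)
}

# lowercase name -> gene_id lookup; systematic names win over aliases
annotation_name_lut <- function(ann) {
  g <- ann$genes
  alias_list <- strsplit(g$aliases, ";", fixed = TRUE)
  alias_n <- lengths(alias_list)
  keys <- c(tolower(g$gene_id), tolower(trimws(unlist(alias_list))))
  vals <- c(g$gene_id, rep(g$gene_id, alias_n))
  keep <- nzchar(keys)
  keys <- keys[keep]; vals <- vals[keep]
  keep_first <- !duplicated(keys)
  stats::setNames(vals[keep_first], keys[keep_first])
}

#' Genomic regions (0-based half-open)
#'
#' @param chrom chromosome id.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; `end - start` is the length in bp.
#' @return A `region` object (list with `chrom`, `start`, `end`).
#' @export
region <- function(chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start > end) {
    stop("invalid region: need 0 <= start <= end")
  }
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "region")
}

gene_record <- function(ann, gene_id) {
  i <- match(gene_id, ann$genes$gene_id)
  if (is.na(i)) stop("gene not in annotation: ", gene_id)
  ann$genes[i, ]
}

#' Promoter region of a gene
#'
#' The promoter spans 500 bp upstream through 100 bp downstream of the start
#' codon, in transcription direction. With `a` the 0-based coordinate of the
#' start codon's first base: `[a-500, a+100)` on the `+` strand and its
#' mirror image `[a-99, a+501)` on the `-` strand. The result is clamped to
#' the chromosome, so the length is 600 bp except near chromosome ends.
#'
#' @param gene_id systematic gene name.
#' @param ann a [annotation()] object.
#' @return A [region()].
#' @export
promoter_region <- function(gene_id, ann) {
  g <- gene_record(ann, gene_id)
  a <- g$start_codon_pos
  if (g$strand == "+") {
    s <- a - 500L; e <- a + 100L
  } else {
    s <- a - 99L; e <- a + 501L
  }
  clamp_region(g$chrom, s, e, ann)
}

#' Coding region of a gene
#'
#' The genome-ordered half-open interval from the start codon to the stop
#' codon, both codons included; strand determines only which anchor is
#' leftmost.
#'
#' @inheritParams promoter_region
#' @return A [region()]; zero-length coding regions are rejected.
#' @export
coding_region <- function(gene_id, ann) {
  g <- gene_record(ann, gene_id)
  if (g$strand == "+") {
    s <- g$start_codon_pos; e <- g$stop_codon_end
  } else {
    s <- g$stop_codon_end + 1L; e <- g$start_codon_pos + 1L
  }
  if (s == e) stop("zero-length coding region for gene ", gene_id)
  region(g$chrom, s, e)
}

clamp_region <- function(chrom, start, end, ann) {
  len <- ann$chrom_lengths[[chrom]]
  if (is.null(len)) stop("unknown chromosome: ", chrom)
  region(chrom, max(0L, start), min(len, max(0L, end)))
}

# All promoter or coding regions of an annotation as a data.frame
# (gene_id, chrom, start, end), vectorised for scoring.
gene_regions <- function(ann, region_kind = c("promoter", "coding")) {
  region_kind <- match.arg(region_kind)
  g <- ann$genes
  a <- g$start_codon_pos
  plus <- g$strand == "+"
  if (region_kind == "promoter") {
    s <- ifelse(plus, a - 500L, a - 99L)
    e <- ifelse(plus, a + 100L, a + 501L)
  } else {
    s <- ifelse(plus, a, g$stop_codon_end + 1L)
    e <- ifelse(plus, g$stop_codon_end, a + 1L)
  }
  len <- ann$chrom_lengths[g$chrom]
  data.frame(
    gene_id = g$gene_id, chrom = g$chrom,
    start = pmax(0L, as.integer(s)),
    end = pmin(as.integer(len), pmax(0L, as.integer(e))),
    stringsAsFactors = FALSE
  )
}
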