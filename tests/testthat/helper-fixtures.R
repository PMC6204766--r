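# Shared fixtures and independent oracles, all built in code.

# Three-gene annotation on two chromosomes, one gene per strand orientation
# plus an aliased gene, used across the annotation/signal/set tests.
tiny_annotation <- function() {
  annotation(
    data.frame(
      gene_id = c("g1", "g2", "g3"),
      aliases = c("", "alpha;ALP1", "beta"),
      chrom = c("chrI", "chrI", "chrII"),
      strand = c("+", "-", "+"),
      start_codon_pos = c(1000L, 5000L, 700L),
      stop_codon_end = c(1900L, 4099L, 1600L),
      stringsAsFactors = FALSE
    ),
    chrom_lengths = c(chrI = 10000L, chrII = 8000L)
  )
}

write_tiny_annotation_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "#chrom_length chrI 10000",
    "#chrom_length chrII 8000",
    paste(c("gene_id", "aliases", "chrom", "strand",
            "start_codon_pos", "stop_codon_end"), collapse = "\t"),
    "g1\t\tchrI\t+\t1000\t1900",
    "g2\talpha;ALP1\tchrI\t-\t5000\t4099",
    "g3\tbeta\tchrII\t+\t700\t1600"
  ), path)
  path
}

# Brute-force per-base maximum: scans every base of the region and takes the
# max over interval values covering it. Independent of the interval-overlap
# path under test.
oracle_max_signal <- function(intervals, r) {
  if (r$end <= r$start) return(NA_real_)
  best <- NA_real_
  for (b in seq.int(r$start, r$end - 1L)) {
    covering <- intervals$chrom == r$chrom &
      intervals$start <= b & b < intervals$end
    if (any(covering)) {
      v <- max(intervals$value[covering])
      best <- if (is.na(best)) v else max(best, v)
    }
  }
  best
}

# Exhaustive hypergeometric oracle for tiny universes: enumerate every
# R-subset of an F-universe containing S marked elements and count overlaps.
oracle_tail_enum <- function(T, R, S, F) {
  if (R == 0L) {
    return(list(pmf0 = as.numeric(T == 0), upper = 1, lower = 1))
  }
  subsets <- utils::combn(F, R)
  overlaps <- colSums(subsets <= S)  # elements 1..S are the marked ones
  list(
    pmf = mean(overlaps == T),
    upper = mean(overlaps >= T),
    lower = mean(overlaps <= T)
  )
}

# Direct binomial-coefficient-ratio pmf (no logs), exact to double rounding
# for F <= 60; used for the full tail sweep.
oracle_pmf_choose <- function(S, R, F) {
  xs <- 0:min(S, R)
  choose(S, xs) * choose(F - S, R - xs) / choose(F, R)
}

# Build an annotation plus per-mark gene sets entirely in memory for
# analyze()-level tests: `n` genes, a focal set of the first `s` ids.
toy_universe <- function(n) {
  ids <- sprintf("u%04d", seq_len(n))
  annotation(
    data.frame(
      gene_id = ids, aliases = "", chrom = "chr1", strand = "+",
      start_codon_pos = 600L + (seq_len(n) - 1L) * 2000L,
      stop_codon_end = 1500L + (seq_len(n) - 1L) * 2000L,
      stringsAsFactors = FALSE
    )
  )
}
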