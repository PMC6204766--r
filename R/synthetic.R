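#' Plan for a synthetic enrichment study
#'
#' Describes a fully synthetic genome, ChIP-style signal tracks with a
#' planted high-signal gene subset per mark, regulator target maps, and an
#' input gene list with a controlled overlap with the first ("focal") mark's
#' planted subset. Everything downstream of the seed is deterministic, so the
#' same plan always generates byte-identical files.
#'
#' Genes are laid out non-overlapping with alternating strands (to exercise
#' strand-aware promoter logic by construction). Interval values are drawn
#' `Normal(signal_high, noise_sd)` inside the planted subset's regions and
#' `Normal(signal_low, noise_sd)` elsewhere; with the default separation
#' (high 3, low 0, sd 0.1) any threshold between the two levels recovers the
#' planted membership exactly. Setting `signal_high == signal_low` makes a
#' mark fully degenerate (no planted structure survives thresholding above
#' both levels), which is useful as an explicit null.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes in the universe.
#' @param n_chroms number of chromosomes.
#' @param gene_spacing distance in bp between successive gene starts; must
#'   leave room for the 600 bp promoter and the signal intervals.
#' @param coding_length coding-region length in bp.
#' @param marks data.frame with columns `name`, `planted_fraction`,
#'   `signal_high`, `signal_low`, `noise_sd`. The first row is the focal
#'   mark from which the input list is drawn; the others act as nulls.
#' @param regulators data.frame with columns `name`, `condition`,
#'   `target_fraction`.
#' @param input_size size of the generated input gene list.
#' @param input_overlap how many input genes come from the focal mark's
#'   planted subset (the rest are drawn outside it).
#' @return A `synthetic_plan` object.
#' @export
synthetic_plan <- function(seed = 1L, n_genes = 1000L, n_chroms = 4L,
                           gene_spacing = 2000L, coding_length = 900L,
                           marks = NULL, regulators = NULL,
                           input_size = 50L, input_overlap = 50L) {
  if (is.null(marks)) {
    marks <- data.frame(
      name = c("markA", "markB", "markC", "markD", "markE"),
      planted_fraction = 0.2,
      signal_high = 3, signal_low = 0, noise_sd = 0.1,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(regulators)) {
    regulators <- data.frame(
      name = rep(c("RegA", "RegB", "RegC"), each = 2L),
      condition = rep(c("25C", "37C"), times = 3L),
      target_fraction = 0.1,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(
    all(marks$planted_fraction >= 0 & marks$planted_fraction <= 1),
    all(marks$signal_high >= marks$signal_low),
    all(regulators$target_fraction >= 0 & regulators$target_fraction <= 1),
    input_overlap <= input_size
  )
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         n_chroms = as.integer(n_chroms),
         gene_spacing = as.integer(gene_spacing),
         coding_length = as.integer(coding_length),
         marks = marks, regulators = regulators,
         input_size = as.integer(input_size),
         input_overlap = as.integer(input_overlap)),
    class = "synthetic_plan"
  )
}

#' Generate a synthetic study on disk
#'
#' Writes, under `out_dir`: `annotation.tsv` (with `#chrom_length`
#' directives), one bedGraph track per mark under `marks/`, a marks manifest
#' `manifest.tsv` for the CLI, `regulators.gmt`, the input gene list
#' `genes.txt` (alternating systematic names and aliases, to exercise name
#' resolution), and `truth.json` recording planted memberships and the
#' expected `T`, `R`, `S`, `F` for the input list.
#'
#' @param plan a [synthetic_plan()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the written `paths` and the parsed `truth`.
#' @export
generate_study <- function(plan, out_dir) {
  stopifnot(inherits(plan, "synthetic_plan"))
  if (plan$gene_spacing < plan$coding_length + 1100L) {
    stop("plan infeasible: gene_spacing must be at least coding_length + 1100")
  }
  if (plan$input_size > plan$n_genes) stop("plan infeasible: input too large")
  set.seed(plan$seed)
  dir.create(file.path(out_dir, "marks"), showWarnings = FALSE,
             recursive = TRUE)

  n <- plan$n_genes
  gpc <- ceiling(n / plan$n_chroms)
  width <- nchar(as.character(n))
  ids <- sprintf(paste0("g%0", width, "d"), seq_len(n))
  aliases <- sprintf("GENE%d", seq_len(n))
  chrom_of <- sprintf("chr%d", ((seq_len(n) - 1L) %/% gpc) + 1L)
  idx_on <- (seq_len(n) - 1L) %% gpc
  slot <- 600L + idx_on * plan$gene_spacing
  strand <- ifelse(seq_len(n) %% 2L == 1L, "+", "-")
  start_codon <- ifelse(strand == "+", slot, slot + plan$coding_length - 1L)
  stop_end <- ifelse(strand == "+", slot + plan$coding_length, slot - 1L)
  chrom_len <- 600L + gpc * plan$gene_spacing + 600L

  ann_path <- file.path(out_dir, "annotation.tsv")
  chroms <- sprintf("chr%d", seq_len(plan$n_chroms))
  con <- file(ann_path, "w")
  writeLines(sprintf("#chrom_length %s %d", chroms, chrom_len), con)
  writeLines(paste(c("gene_id", "aliases", "chrom", "strand",
                     "start_codon_pos", "stop_codon_end"), collapse = "\t"),
             con)
  writeLines(paste(ids, aliases, chrom_of, strand, start_codon, stop_end,
                   sep = "\t"), con)
  close(con)

  # strand-aware signal placement: one interval 300-400 bp upstream of the
  # start codon (inside the promoter only) and one 200-300 bp downstream
  # (inside the coding region only)
  prom_start <- ifelse(strand == "+", start_codon - 400L, start_codon + 301L)
  cod_start <- ifelse(strand == "+", start_codon + 200L, start_codon - 299L)

  truth_marks <- list()
  manifest <- data.frame(name = character(0), file = character(0),
                         format = character(0), value_kind = character(0),
                         condition = character(0), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(plan$marks))) {
    m <- plan$marks[k, ]
    n_plant <- round(m$planted_fraction * n)
    planted <- sort(sample(ids, n_plant))
    is_planted <- ids %in% planted
    mu <- ifelse(is_planted, m$signal_high, m$signal_low)
    val_prom <- stats::rnorm(n, mean = mu, sd = m$noise_sd)
    val_cod <- stats::rnorm(n, mean = mu, sd = m$noise_sd)
    iv <- data.frame(
      chrom = c(chrom_of, chrom_of),
      start = c(prom_start, cod_start),
      end = c(prom_start + 100L, cod_start + 100L),
      value = c(val_prom, val_cod),
      stringsAsFactors = FALSE
    )
    iv <- iv[order(iv$chrom, iv$start, method = "radix"), ]
    track <- file.path(out_dir, "marks", paste0(m$name, ".bedGraph"))
    writeLines(sprintf("%s\t%d\t%d\t%.6f", iv$chrom, iv$start, iv$end,
                       iv$value), track)
    manifest <- rbind(manifest, data.frame(
      name = m$name, file = file.path("marks", paste0(m$name, ".bedGraph")),
      format = "bedgraph",
      value_kind = sprintf("log2(%s/control)", m$name),
      condition = "", stringsAsFactors = FALSE
    ))
    truth_marks[[k]] <- list(
      name = m$name, focal = (k == 1L), planted = planted, S = n_plant
    )
  }
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  reg_lines <- character(nrow(plan$regulators))
  truth_regs <- list()
  for (k in seq_len(nrow(plan$regulators))) {
    r <- plan$regulators[k, ]
    targets <- sort(sample(ids, round(r$target_fraction * n)))
    reg_lines[k] <- paste(c(paste(r$name, r$condition, sep = "_"),
                            "synthetic targets", targets), collapse = "\t")
    truth_regs[[k]] <- list(name = r$name, condition = r$condition,
                            members = targets)
  }
  reg_path <- file.path(out_dir, "regulators.gmt")
  writeLines(reg_lines, reg_path)

  focal_planted <- truth_marks[[1L]]$planted
  inside <- sample(focal_planted, plan$input_overlap)
  outside <- sample(setdiff(ids, focal_planted),
                    plan$input_size - plan$input_overlap)
  input_genes <- c(inside, outside)
  # alternate systematic names and aliases in the written list
  as_alias <- seq_along(input_genes) %% 2L == 0L
  written_names <- ifelse(as_alias, aliases[match(input_genes, ids)],
                          input_genes)
  genes_path <- file.path(out_dir, "genes.txt")
  writeLines(written_names, genes_path)

  focal_T <- length(intersect(input_genes, focal_planted))
  truth <- list(
    seed = plan$seed, F = n, R = plan$input_size,
    input = list(genes = input_genes, overlap = plan$input_overlap),
    expected_counts = list(T = focal_T, R = plan$input_size,
                           S = truth_marks[[1L]]$S, F = n),
    focal_mark = plan$marks$name[1L],
    expected_focal_trend =
      if (plan$input_overlap == plan$input_size) "enriched"
      else if (plan$input_overlap == 0L) "depleted"
      else "unspecified",
    marks = truth_marks,
    regulators = truth_regs
  )
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(
    paths = list(annotation = ann_path, manifest = file.path(out_dir,
                 "manifest.tsv"), regulators = reg_path, genes = genes_path,
                 truth = truth_path, dir = out_dir),
    truth = truth
  ))
}

#' Compare analysis results against a synthetic study's planted truth
#'
#' Checks that the focal mark is called with its expected trend in both
#' region kinds (sensitivity) and that no null mark is called at all
#' (false-call count). Regulator rows are counted as false calls too, since
#' the generated input list is random with respect to the regulator maps.
#'
#' @param truth the `truth` list returned by [generate_study()], or the path
#'   to its `truth.json`.
#' @param results an `enrichment_results` data.frame from [analyze()] run on
#'   the generated study.
#' @return A list with `sensitivity` (fraction of focal-mark hypotheses
#'   recovered with the expected trend), `false_calls` (count of significant
#'   non-focal rows), and a `details` data.frame.
#' @export
recovery_check <- function(truth, results) {
  if (is.character(truth)) truth <- jsonlite::fromJSON(truth,
                                                       simplifyVector = FALSE)
  stopifnot(inherits(results, "enrichment_results"))
  mark_names <- vapply(truth$marks, function(m) m$name, "")
  mark_rows <- results[results$family %in% c("marks_promoter", "marks_coding"), ]
  if (!setequal(unique(mark_rows$label), mark_names)) {
    stop("mark labels in results do not match the truth record")
  }
  expected <- truth$expected_focal_trend
  if (identical(expected, "unspecified")) {
    stop("recovery_check needs an input list fully inside or fully outside ",
         "the focal planted set")
  }
  focal <- mark_rows$label == truth$focal_mark
  recovered <- mark_rows$trend[focal] == expected
  false_mark <- sum(mark_rows$significant[!focal])
  reg_rows <- results[results$family == "regulators", ]
  false_reg <- sum(reg_rows$significant)
  details <- data.frame(
    label = c(mark_rows$label, reg_rows$label),
    region = c(mark_rows$region, reg_rows$region),
    family = c(mark_rows$family, reg_rows$family),
    trend = c(mark_rows$trend, reg_rows$trend),
    expected = c(ifelse(focal, expected, "none"),
                 rep("none", nrow(reg_rows))),
    stringsAsFactors = FALSE
  )
  list(
    sensitivity = mean(recovered),
    false_calls = false_mark + false_reg,
    details = details
  )
}
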