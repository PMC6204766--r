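#' Overlap counts for a hypergeometric enrichment test
#'
#' The four integers of an over-representation test: `T = |S intersect R|`
#' genes of the input list that carry the mark, out of an input list of size
#' `R`, a mark set of size `S`, and a gene universe of size `F` (6572 for the
#' yeast genome in the reference datasets).
#'
#' @param T overlap size, `0 <= T <= min(S, R)`.
#' @param R input-list size, `R <= F`.
#' @param S gene-set size, `S <= F`.
#' @param F universe size.
#' @return An object of class `overlap_counts`.
#' @export
overlap_counts <- function(T, R, S, F) {
  v <- c(T = T, R = R, S = S, F = F)
  if (anyNA(v) || any(v != round(v)) || any(v < 0)) {
    stop("counts must be non-negative integers")
  }
  T <- as.numeric(T); R <- as.numeric(R); S <- as.numeric(S); F <- as.numeric(F)
  if (S > F || R > F) stop("S and R must not exceed the universe size F")
  if (T > min(S, R)) stop("T must not exceed min(S, R)")
  structure(list(T = T, R = R, S = S, F = F), class = "overlap_counts")
}

as_counts <- function(c) {
  if (inherits(c, "overlap_counts")) c
  else overlap_counts(c$T, c$R, c$S, c$F)
}

#' Natural-log hypergeometric probability mass
#'
#' `ln[ C(S,x) * C(F-S, R-x) / C(F,R) ]`, computed with log binomial
#' coefficients so that genome-scale counts never overflow. Outcomes outside
#' the support (e.g. `R - x > F - S`) have probability zero and return
#' `-Inf`.
#'
#' @param x overlap size(s); vectorised.
#' @param c an [overlap_counts()] (its `T` is ignored here).
#' @return Numeric vector of natural-log probabilities.
#' @export
log_hypergeom_pmf <- function(x, c) {
  c <- as_counts(c)
  if (any(x != round(x)) || any(x < 0) || any(x > min(c$S, c$R))) {
    stop("x must be an integer in [0, min(S, R)]")
  }
  out <- rep(-Inf, length(x))
  ok <- (c$R - x) <= (c$F - c$S)
  out[ok] <- lchoose(c$S, x[ok]) + lchoose(c$F - c$S, c$R - x[ok]) -
    lchoose(c$F, c$R)
  out
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Hypergeometric enrichment p-value (upper tail)
#'
#' `P(x >= T)`: the probability, when `R` genes are drawn without replacement
#' from a universe of `F` genes of which `S` carry the mark, of observing at
#' least the overlap actually seen. The tail is accumulated in log space;
#' values below double precision underflow to exactly 0, which is reported
#' as such.
#'
#' @param c an [overlap_counts()].
#' @return p-value in `[0, 1]`.
#' @export
p_enrichment <- function(c) {
  c <- as_counts(c)
  xs <- seq.int(c$T, min(c$S, c$R))
  p <- exp(logsumexp(log_hypergeom_pmf(xs, c)))
  min(max(p, 0), 1)
}

#' Hypergeometric depletion p-value (lower tail)
#'
#' `P(x <= T)`, the lower-tail counterpart of [p_enrichment()], with the same
#' log-space accumulation and underflow behaviour.
#'
#' @param c an [overlap_counts()].
#' @return p-value in `[0, 1]`.
#' @export
p_depletion <- function(c) {
  c <- as_counts(c)
  xs <- seq.int(0, c$T)
  p <- exp(logsumexp(log_hypergeom_pmf(xs, c)))
  min(max(p, 0), 1)
}

#' Multiple-testing correction
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up adjusted
#' values, in the input order; `"none"` is the identity.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"`, `"fdr"` (Benjamini-Hochberg) or `"none"`.
#' @return Numeric vector of corrected p-values, same order as the input.
#' @export
correct_pvalues <- function(p, method = c("bonferroni", "fdr", "none")) {
  method <- match.arg(method)
  if (length(p) < 1L) stop("need at least one p-value")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  switch(method,
         bonferroni = stats::p.adjust(p, method = "bonferroni"),
         fdr = stats::p.adjust(p, method = "BH"),
         none = p)
}

#' Enrichment statistics from overlap counts
#'
#' Computes both raw tail p-values, the fold enrichment
#' `(T/R) / (S/F)` (0 when `T = 0`), and the observed (`T/R`) and expected
#' (`S/F`) ratios. Sets with `S = 0` are flagged untestable rather than
#' erroring. The trend is left undecided (`"none"`) until a correction and
#' significance level are applied by [analyze()].
#'
#' @param label mark or regulator name.
#' @param counts an [overlap_counts()].
#' @param region_kind,condition carried through to the result row.
#' @return A one-row data.frame with columns `label`, `region`, `condition`,
#'   `T`, `R`, `S`, `F`, `p_enrich_raw`, `p_deplete_raw`, `fold_enrichment`,
#'   `observed_ratio`, `expected_ratio`, `untestable`.
#' @export
enrichment_from_counts <- function(label, counts, region_kind = NA_character_,
                                   condition = NA_character_) {
  c <- as_counts(counts)
  untestable <- c$S == 0
  observed <- if (c$R > 0) c$T / c$R else NA_real_
  expected <- c$S / c$F
  fold <- if (untestable) NA_real_
          else if (c$T == 0) 0
          else observed / expected
  data.frame(
    label = label, region = region_kind, condition = condition,
    T = c$T, R = c$R, S = c$S, F = c$F,
    p_enrich_raw = if (untestable) NA_real_ else p_enrichment(c),
    p_deplete_raw = if (untestable) NA_real_ else p_depletion(c),
    fold_enrichment = fold,
    observed_ratio = observed,
    expected_ratio = expected,
    untestable = untestable,
    stringsAsFactors = FALSE
  )
}

#' Enrichment/depletion analysis of a gene list
#'
#' The core procedure: for every mark set, both the enrichment and the
#' depletion tails are tested (for promoter and coding sets separately); for
#' every regulator set only enrichment is tested. Multiple-testing correction
#' is applied within three separate hypothesis families — marks x promoter,
#' marks x coding, and regulators — with the two tails of a mark counted as
#' separate hypotheses in its family. Raw tail p-values are always reported
#' alongside the corrected ones.
#'
#' A result's trend is `"enriched"` (`"depleted"`) when its corrected
#' enrichment (depletion) p-value falls below `alpha`. Should both tails pass
#' (possible only in pathological tiny universes), the tail with the smaller
#' raw p-value is reported and a warning is emitted.
#'
#' @param gene_list character vector of resolved systematic gene ids (use
#'   [resolve_gene_names()] first); every id must be in the universe.
#' @param mark_sets list of [gene_set()]s from [build_mark_set()] (any mix of
#'   promoter and coding sets).
#' @param regulator_sets list of promoter-binding [gene_set()]s, or `NULL`.
#' @param ann a [annotation()] defining the universe `F`.
#' @param correction `"bonferroni"`, `"fdr"` or `"none"`.
#' @param alpha significance level on the corrected p-value (default 0.01);
#'   `NULL` labels every trend `"none"` and defers the call to the reader.
#' @return A data.frame of class `enrichment_results`, one row per tested
#'   set, with both raw tails, both corrected tails, the selected-tail
#'   `p_raw`/`p_corrected`, `trend`, fold and ratio columns, and a
#'   `significant` flag. The `alpha` and `correction` used are attached as
#'   attributes.
#' @export
analyze <- function(gene_list, mark_sets, regulator_sets = NULL, ann,
                    correction = c("bonferroni", "fdr", "none"),
                    alpha = 0.01) {
  correction <- match.arg(correction)
  stopifnot(inherits(ann, "yeast_annotation"))
  gene_list <- unique(as.character(gene_list))
  if (length(gene_list) == 0L) stop("empty gene list")
  absent <- setdiff(gene_list, ann$genes$gene_id)
  if (length(absent) > 0L) {
    stop("gene list contains ids absent from the universe (resolve names ",
         "first): ", paste(utils::head(absent, 5L), collapse = ", "))
  }
  if (!is.null(alpha) && (alpha <= 0 || alpha > 1)) {
    stop("alpha must lie in (0, 1]")
  }

  one_family <- function(sets, family, tails) {
    if (length(sets) == 0L) return(NULL)
    rows <- do.call(rbind, lapply(sets, function(s) {
      counts <- overlap_counts(
        T = length(intersect(s$members, gene_list)),
        R = length(gene_list), S = length(s$members), F = ann$F
      )
      enrichment_from_counts(s$label, counts, s$region_kind, s$condition)
    }))
    rows$family <- family
    testable <- !rows$untestable
    rows$p_enrich_corrected <- NA_real_
    rows$p_deplete_corrected <- NA_real_
    if (any(testable)) {
      if (tails == 2L) {
        raw <- c(rows$p_enrich_raw[testable], rows$p_deplete_raw[testable])
        adj <- correct_pvalues(raw, correction)
        m <- sum(testable)
        rows$p_enrich_corrected[testable] <- adj[seq_len(m)]
        rows$p_deplete_corrected[testable] <- adj[m + seq_len(m)]
      } else {
        rows$p_enrich_corrected[testable] <-
          correct_pvalues(rows$p_enrich_raw[testable], correction)
      }
    }
    rows
  }

  mark_sets <- mark_sets %||% list()
  kinds <- vapply(mark_sets, function(s) s$region_kind, "")
  res <- rbind(
    one_family(mark_sets[kinds == "promoter"], "marks_promoter", 2L),
    one_family(mark_sets[kinds == "coding"], "marks_coding", 2L),
    one_family(regulator_sets %||% list(), "regulators", 1L)
  )
  if (is.null(res)) stop("no gene sets supplied")

  alpha_eff <- if (is.null(alpha)) -Inf else alpha
  enr <- !is.na(res$p_enrich_corrected) & res$p_enrich_corrected < alpha_eff
  dep <- !is.na(res$p_deplete_corrected) & res$p_deplete_corrected < alpha_eff
  both <- enr & dep
  if (any(both)) {
    warning("both tails significant for: ",
            paste(res$label[both], collapse = ", "),
            "; reporting the smaller-p tail")
    keep_enr <- res$p_enrich_raw[both] <= res$p_deplete_raw[both]
    dep[both][keep_enr] <- FALSE
    enr[both][!keep_enr] <- FALSE
  }
  res$trend <- ifelse(enr, "enriched", ifelse(dep, "depleted", "none"))
  res$significant <- res$trend != "none"

  # selected tail: the called one, else (marks) the smaller raw p, else
  # enrichment for regulator rows
  use_dep <- dep | (!enr & res$family != "regulators" &
                      !is.na(res$p_deplete_raw) & !is.na(res$p_enrich_raw) &
                      res$p_deplete_raw < res$p_enrich_raw)
  res$p_raw <- ifelse(use_dep, res$p_deplete_raw, res$p_enrich_raw)
  res$p_corrected <- ifelse(use_dep, res$p_deplete_corrected,
                            res$p_enrich_corrected)
  rownames(res) <- NULL
  structure(res, class = c("enrichment_results", "data.frame"),
            alpha = alpha, correction = correction)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format a p-value the way the result tables display it
#'
#' Scientific notation with 3 significant figures; exact zero prints `"0"`.
#' @param p numeric vector.
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  out <- ifelse(is.na(p), "NA",
         ifelse(p == 0, "0", formatC(signif(p, 3), format = "e", digits = 2)))
  sub("e([+-])0(\\d\\d)$", "e\\1\\2", out)
}

#' Format a ratio as a percentage with 2 decimal places
#' @param x numeric vector of ratios in `[0, 1]`.
#' @return character vector like `"95.40%"`.
#' @export
format_percent <- function(x) {
  ifelse(is.na(x), "NA", paste0(formatC(100 * x, format = "f", digits = 2), "%"))
}

#' Format a fold enrichment with 2 decimal places
#' @param x numeric vector.
#' @return character vector.
#' @export
format_fold <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 2))
}
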