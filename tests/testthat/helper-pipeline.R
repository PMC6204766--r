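# Run the full analysis pipeline over a generated synthetic study directory.
run_study_analysis <- function(dir, threshold = 1, correction = "bonferroni",
                               alpha = 0.01, with_regulators = FALSE) {
  ann <- load_annotation(file.path(dir, "annotation.tsv"), "tsv")
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  mark_sets <- list()
  for (k in seq_len(nrow(manifest))) {
    ds <- read_signal(file.path(dir, manifest$file[k]), "bedgraph",
                      name = manifest$name[k])
    mark_sets <- c(mark_sets, list(
      build_mark_set(score_genes(ds, ann, "promoter"), threshold),
      build_mark_set(score_genes(ds, ann, "coding"), threshold)
    ))
  }
  regs <- if (with_regulators) {
    load_regulator_targets(file.path(dir, "regulators.gmt"), "gmt", ann)
  } else {
    NULL
  }
  input <- resolve_gene_names(
    read_gene_list(file.path(dir, "genes.txt")), ann)$resolved
  analyze(input, mark_sets, regs, ann, correction, alpha)
}
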