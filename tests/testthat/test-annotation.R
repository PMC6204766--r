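test_that("TSV loading builds a validated annotation and rejects bad input", {
  path <- write_tiny_annotation_tsv()
  ann <- load_annotation(path, "tsv")
  expect_s3_class(ann, "yeast_annotation")
  expect_identical(ann$F, 3L)
  expect_identical(ann$chrom_lengths[["chrI"]], 10000L)
  expect_identical(ann$genes$strand, c("+", "-", "+"))

  dup <- tempfile(fileext = ".tsv")
  writeLines(c(
    "gene_id\taliases\tchrom\tstrand\tstart_codon_pos\tstop_codon_end",
    "g1\t\tchrI\t+\t100\t400",
    "g1\t\tchrI\t+\t900\t1200"
  ), dup)
  expect_error(load_annotation(dup, "tsv"), "duplicate gene_id")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c(
    "gene_id\taliases\tchrom\tstrand\tstart_codon_pos\tstop_codon_end",
    "g1\t\tchrI\t+\tnotanumber\t400"
  ), bad)
  expect_error(load_annotation(bad, "tsv"), "line 2")

  outside <- data.frame(gene_id = "g1", aliases = "", chrom = "chrI",
                        strand = "+", start_codon_pos = 100L,
                        stop_codon_end = 999L)
  expect_error(annotation(outside, chrom_lengths = c(chrI = 500L)),
               "outside chromosome")
  expect_error(annotation(transform(outside, strand = "х")), "strand")
})

test_that("GFF3 genes round-trip strand and codon anchors", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chrI 1 10000",
    paste("chrI", "test", "gene", "1001", "1900", ".", "+", ".",
          "ID=gp;Name=PLUS1", sep = "\t"),
    paste("chrI", "test", "gene", "4100", "5000", ".", "-", ".",
          "ID=gm;Alias=MINUS1", sep = "\t")
  ), gff)
  ann <- load_annotation(gff, "gff3")
  expect_identical(ann$F, 2L)
  expect_identical(ann$chrom_lengths[["chrI"]], 10000L)
  g <- ann$genes
  expect_identical(g$strand[g$gene_id == "gp"], "+")
  expect_identical(g$strand[g$gene_id == "gm"], "-")
  # 1-based inclusive converted to 0-based codon anchors
  expect_identical(g$start_codon_pos[g$gene_id == "gp"], 1000L)
  expect_identical(g$stop_codon_end[g$gene_id == "gp"], 1900L)
  expect_identical(g$start_codon_pos[g$gene_id == "gm"], 4999L)
  expect_identical(g$stop_codon_end[g$gene_id == "gm"], 4098L)
  # aliases are resolvable
  expect_identical(resolve_gene_names("minus1", ann)$resolved, "gm")
})

test_that("gene name resolution trims, ignores case, collapses duplicates", {
  ann <- tiny_annotation()
  r <- resolve_gene_names(c("g1", "G1", " g1 "), ann)
  expect_identical(r$resolved, "g1")
  expect_identical(r$unresolved, character(0))

  r <- resolve_gene_names("alpha", ann)
  expect_identical(r$resolved, "g2")

  r <- resolve_gene_names(c("nosuchgene", "beta", "NoSuchGene"), ann)
  expect_identical(r$resolved, "g3")
  expect_identical(r$unresolved, "nosuchgene")

  # every distinct input name is accounted for
  inputs <- c("g1", "alpha", "ALP1", "missing1", "missing2", "G1")
  r <- resolve_gene_names(inputs, ann)
  expect_identical(length(r$resolved) + length(r$unresolved), 4L)

  # idempotence: resolving the resolved set returns itself
  r2 <- resolve_gene_names(r$resolved, ann)
  expect_identical(r2$resolved, r$resolved)
  expect_identical(r2$unresolved, character(0))

  expect_error(resolve_gene_names(character(0), ann), "no genes supplied")
  expect_error(resolve_gene_names(c("", "  "), ann), "no genes supplied")
})

test_that("promoter regions follow the strand-aware 600 bp convention", {
  ann <- tiny_annotation()
  p1 <- promoter_region("g1", ann)   # + strand, a = 1000
  expect_identical(c(p1$start, p1$end), c(500L, 1100L))
  p2 <- promoter_region("g2", ann)   # - strand, a = 5000
  expect_identical(c(p2$start, p2$end), c(4901L, 5501L))
  expect_identical(p2$end - p2$start, 600L)

  # clamping at the left chromosome edge
  ann_edge <- annotation(
    data.frame(gene_id = "e1", aliases = "", chrom = "c", strand = "+",
               start_codon_pos = 100L, stop_codon_end = 400L),
    chrom_lengths = c(c = 1000L)
  )
  pe <- promoter_region("e1", ann_edge)
  expect_identical(c(pe$start, pe$end), c(0L, 200L))

  # clamping at the right edge for a minus-strand gene
  ann_edge2 <- annotation(
    data.frame(gene_id = "e2", aliases = "", chrom = "c", strand = "-",
               start_codon_pos = 899L, stop_codon_end = 599L),
    chrom_lengths = c(c = 1000L)
  )
  pe2 <- promoter_region("e2", ann_edge2)
  expect_identical(c(pe2$start, pe2$end), c(800L, 1000L))

  # length is exactly 600 whenever no clamping can occur
  for (g in c("g1", "g2", "g3")) {
    p <- promoter_region(g, ann)
    expect_identical(p$end - p$start, 600L)
  }
})

test_that("coding regions span start to stop codon in genome order", {
  ann <- tiny_annotation()
  c1 <- coding_region("g1", ann)
  expect_identical(c(c1$start, c1$end), c(1000L, 1900L))
  # the minus-strand mirror of the same anchors gives the same interval
  c2 <- coding_region("g2", ann)   # start codon base 5000, stop ends at 4100
  expect_identical(c(c2$start, c2$end), c(4100L, 5001L))
  expect_identical(c2$end - c2$start, 901L)

  # a zero-length coding region cannot be constructed
  expect_error(region("c", 5, 4), "invalid region")
  expect_error(annotation(
    data.frame(gene_id = "z", aliases = "", chrom = "c", strand = "+",
               start_codon_pos = 10L, stop_codon_end = 10L)
  ), "start_codon_pos must be")
})

test_that("reflecting an annotation mirrors promoters and coding regions", {
  ann <- tiny_annotation()
  L <- 10000L  # put both mirrored chromosomes at the same length
  ann_len <- annotation(ann$genes, chrom_lengths = c(chrI = L, chrII = L))
  g <- ann_len$genes
  mirrored <- data.frame(
    gene_id = g$gene_id, aliases = g$aliases, chrom = g$chrom,
    strand = ifelse(g$strand == "+", "-", "+"),
    # both codon anchors mirror like positions (x -> L-1-x): the flip of
    # transcription direction carries the exclusivity over automatically
    start_codon_pos = L - 1L - g$start_codon_pos,
    stop_codon_end = L - 1L - g$stop_codon_end,
    stringsAsFactors = FALSE
  )
  ann_m <- annotation(mirrored, chrom_lengths = c(chrI = L, chrII = L))
  for (id in g$gene_id) {
    for (fn in c(promoter_region, coding_region)) {
      r <- fn(id, ann_len)
      rm_ <- fn(id, ann_m)
      expect_identical(rm_$start, L - r$end)
      expect_identical(rm_$end, L - r$start)
    }
  }
})
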