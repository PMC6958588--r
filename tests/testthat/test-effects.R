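test_that("hand-built codon examples classify correctly", {
  toy <- toy_gene_genome("ATGGCTTAA")          # Met-Ala-stop
  # codon 2 GCT -> ACT: Ala -> Thr
  v1 <- data.frame(chrom = "chr1A", pos = 10L, ref = "G", alt = "A")
  c1 <- classify_effect(v1, toy$genes, toy$genome)
  expect_equal(c1$effect, "non_synonymous")
  expect_equal(c1$aa_before, "A")
  expect_equal(c1$aa_after, "T")
  # codon 2 third base GCT -> GCC: synonymous
  v2 <- data.frame(chrom = "chr1A", pos = 12L, ref = "T", alt = "C")
  c2 <- classify_effect(v2, toy$genes, toy$genome)
  expect_equal(c2$effect, "synonymous")
  expect_equal(c2$aa_before, c2$aa_after)

  # TGG codon with G>A at its third base -> TGA: Trp -> stop, and the
  # triggering change is EMS-canonical
  toy2 <- toy_gene_genome("ATGTGGTAA")
  v3 <- data.frame(chrom = "chr1A", pos = 12L, ref = "G", alt = "A")
  c3 <- classify_effect(v3, toy2$genes, toy2$genome)
  expect_equal(c3$effect, "nonsense")
  expect_equal(c3$aa_after, "*")
  expect_true(classify_substitution(c3$ref, c3$alt)$ems_canonical)
})

test_that("minus-strand genes read substitutions on the coding strand", {
  plus <- toy_gene_genome("ATGGCTTAA", strand = "+")
  minus <- toy_gene_genome("ATGGCTTAA", strand = "-")
  # same coding change (codon 2 GCT->ACT) expressed on each strand:
  # on the minus-strand layout the genomic interval is the reverse
  # complement, so the coding G sits as a C on the reference strand
  vp <- data.frame(chrom = "chr1A", pos = 10L, ref = "G", alt = "A")
  # coding position 4 maps to genomic position end - 4 + 1 = 12
  vm <- data.frame(chrom = "chr1A", pos = 12L, ref = "C", alt = "T")
  cp <- classify_effect(vp, plus$genes, plus$genome)
  cm <- classify_effect(vm, minus$genes, minus$genome)
  expect_equal(cm$effect, cp$effect)
  expect_equal(cm$codon_before, cp$codon_before)
  expect_equal(cm$codon_after, cp$codon_after)
})

test_that("variants outside any CDS are non_coding and stop-loss is flagged", {
  toy <- toy_gene_genome("ATGGCTTAA")
  v <- data.frame(chrom = "chr1A", pos = 2L, ref = "T", alt = "A")
  expect_equal(classify_effect(v, toy$genes, toy$genome)$effect,
               "non_coding")
  # TAA -> CAA: stop lost, reported as non_synonymous with the flag
  v2 <- data.frame(chrom = "chr1A", pos = 13L, ref = "T", alt = "C")
  c2 <- classify_effect(v2, toy$genes, toy$genome)
  expect_equal(c2$effect, "non_synonymous")
  expect_true(c2$stop_lost)
})

test_that("a reference mismatch raises a data-integrity error", {
  toy <- toy_gene_genome("ATGGCTTAA")
  v <- data.frame(chrom = "chr1A", pos = 10L, ref = "C", alt = "A")
  expect_error(classify_effect(v, toy$genes, toy$genome),
               "reference mismatch")
})

test_that("classifier agrees with whole-CDS retranslation on simulated genes", {
  spec <- data.frame(name = c("chr1A", "chr1B", "chr1D"),
                     subgenome = c("A", "B", "D"),
                     length = c(30000L, 32000L, 28000L))
  cfg <- sim_config(seed = 81, chromosome_spec = spec)
  gm <- make_gene_models(make_genome(cfg), n_genes = 40, seed = 82)
  genes <- gm$genes
  # sample 300 positions inside CDS intervals, both strands represented
  set.seed(83)
  rows <- genes[sample(nrow(genes), 300, replace = TRUE,
                       prob = genes$end - genes$start + 1), ]
  pos <- rows$start + floor(runif(300) * (rows$end - rows$start + 1))
  v <- data.frame(chrom = rows$chrom, pos = as.integer(pos))
  v <- v[!duplicated(v), ]
  v$ref <- emschar:::genome_base(gm$genome, v$chrom, v$pos)
  v$alt <- vapply(v$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))
  calls <- classify_effect(v, genes, gm$genome)
  coding <- calls[calls$effect != "non_coding", ]
  expect_gt(nrow(coding), 100L)
  expect_true(any(genes$strand[match(coding$gene_id, genes$gene_id)] == "-"))
  for (i in seq_len(nrow(coding))) {
    expect_equal(coding$effect[i],
                 oracle_effect(gm$genome, genes, coding$chrom[i],
                               coding$pos[i], coding$alt[i],
                               coding$gene_id[i]))
  }
})

test_that("effect fractions count over coding calls only", {
  calls <- data.frame(
    chrom = "c", pos = 1:5, ref = "G", alt = "A", gene_id = "g",
    effect = c("synonymous", "synonymous", "non_synonymous", "nonsense",
               "non_coding"),
    stringsAsFactors = FALSE)
  ef <- effect_fractions(calls)
  expect_equal(ef$n_coding, 4L)
  expect_equal(ef$n_non_coding, 1L)
  expect_equal(unname(ef$fractions),
               c(50, 25, 25))
  expect_equal(ef$nonsyn_syn_ratio, 0.5)
  # all non-coding: fractions absent, not zero
  nc <- calls[calls$effect == "non_coding", ]
  ef2 <- effect_fractions(nc)
  expect_true(all(is.na(ef2$fractions)))
  expect_error(effect_fractions(calls[0, ]), "no effect calls")
})

test_that("overlapping gene calls resolve to the most severe class", {
  calls <- data.frame(
    chrom = "c", pos = c(1L, 1L, 2L, 2L), ref = "G", alt = "A",
    gene_id = c("g1", "g2", "g1", "g2"),
    effect = c("synonymous", "nonsense", "synonymous", "non_synonymous"),
    stringsAsFactors = FALSE)
  ef <- effect_fractions(calls)
  expect_equal(ef$n_coding, 2L)
  expect_equal(unname(ef$fractions["nonsense"]), 50)
  expect_equal(unname(ef$fractions["non_synonymous"]), 50)
})
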