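test_that("make_genome honours requested lengths and is seed-deterministic", {
  spec <- data.frame(name = c("chr1A", "chr1B", "chr1D"),
                     subgenome = c("A", "B", "D"),
                     length = c(10000L, 12000L, 8000L))
  cfg <- sim_config(seed = 7, chromosome_spec = spec)
  g <- make_genome(cfg)
  expect_equal(g$chrom$length, spec$length)
  expect_equal(sum(g$chrom$length), 30000L)
  expect_equal(g$chrom$name[which.max(g$chrom$length)], "chr1B")
  expect_true(all(strsplit(as.character(g$seq[[1]]), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  g2 <- make_genome(sim_config(seed = 7, chromosome_spec = spec))
  expect_identical(as.character(g$seq), as.character(g2$seq))
  g3 <- make_genome(sim_config(seed = 8, chromosome_spec = spec))
  expect_false(identical(as.character(g$seq), as.character(g3$seq)))
})

test_that("default sub-genome totals preserve the B > A > D size order", {
  g <- make_genome(sim_config(seed = 1))
  sg <- subgenome_lengths(g)
  len <- setNames(sg$length, sg$subgenome)
  expect_true(len[["B"]] > len[["A"]])
  expect_true(len[["A"]] > len[["D"]])
})

test_that("configuration validation rejects impossible inputs", {
  bad <- data.frame(name = "chr1A", subgenome = "A", length = 0L)
  expect_error(sim_config(seed = 1, chromosome_spec = bad), "length")
  expect_error(sim_config(seed = 1, mutation_density = 0), "density")
  s <- default_spectrum(); s[1] <- s[1] + 0.01
  expect_error(sim_config(seed = 1, spectrum = s), "sum to 1")
  bad_sg <- data.frame(name = "chr1X", subgenome = "X", length = 100L)
  expect_error(sim_config(seed = 1, chromosome_spec = bad_sg), "label")
})

test_that("gene models are well-formed ORFs on both strands", {
  cfg <- sim_config(seed = 3)
  g <- make_genome(cfg)
  gm <- make_gene_models(g, n_genes = 20, seed = 4)
  expect_equal(length(unique(gm$genes$gene_id)), 20L)
  expect_true(all(c("+", "-") %in% gm$genes$strand))
  for (id in unique(gm$genes$gene_id)) {
    cds <- spliced_cds(gm$genome, gm$genes, id)
    expect_equal(length(cds) %% 3L, 0L)
    expect_equal(as.character(Biostrings::subseq(cds, 1, 3)), "ATG")
    aa <- strsplit(as.character(Biostrings::translate(
      cds, no.init.codon = TRUE)), "")[[1]]
    expect_equal(which(aa == "*"), length(aa))  # exactly one terminal stop
  }
  # no two intervals of different genes overlap
  by_chrom <- split(gm$genes, gm$genes$chrom)
  for (gg in by_chrom) {
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1L) expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }
})

test_that("minus-strand genes follow the reverse-complement convention", {
  cfg <- sim_config(seed = 3)
  gm <- make_gene_models(make_genome(cfg), n_genes = 20, seed = 4)
  minus <- gm$genes[gm$genes$strand == "-", ]
  expect_gt(nrow(minus), 0L)
  id <- minus$gene_id[1]
  g <- gm$genes[gm$genes$gene_id == id, ]
  g <- g[order(g$start), ]
  genomic <- paste(vapply(seq_len(nrow(g)), function(i) {
    as.character(Biostrings::subseq(gm$genome$seq[[g$chrom[1]]],
                                    g$start[i], g$end[i]))
  }, character(1)), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genomic)))
  expect_equal(substr(rc, 1, 3), "ATG")
})

test_that("n_genes = 0 yields an empty gene table", {
  g <- make_genome(tiny_cfg())
  gm <- make_gene_models(g, n_genes = 0, seed = 1)
  expect_equal(nrow(gm$genes), 0L)
  expect_identical(as.character(gm$genome$seq), as.character(g$seq))
})

test_that("population simulation accounting is exact", {
  cfg <- tiny_cfg(seed = 21, noise_fraction = 0.1)
  g <- make_genome(cfg)
  pop <- simulate_ems_population(g, cfg)
  tr <- pop$truth
  for (s in names(pop$samples)) {
    n_emitted <- n_variants(pop$samples[[s]])
    n_parts <- sum(tr$induced$sample == s) + nrow(tr$background) +
      sum(tr$noise$sample == s)
    expect_equal(n_emitted, n_parts)
    # induced refs match the reference genome
    ind <- tr$induced[tr$induced$sample == s, ]
    expect_equal(emschar:::genome_base(g, ind$chrom, ind$pos), ind$ref)
    # induced disjoint from background (full key)
    ik <- paste(ind$chrom, ind$pos, ind$ref, ind$alt)
    bk <- paste(tr$background$chrom, tr$background$pos,
                tr$background$ref, tr$background$alt)
    expect_length(intersect(ik, bk), 0L)
  }
  # noise records and only noise records fail the strict filters
  for (s in names(pop$samples)) {
    v <- pop$samples[[s]]$variants
    fails <- v$dp <= 5 | v$qual <= 20
    expect_equal(sum(fails), sum(tr$noise$sample == s))
  }
})

test_that("a degenerate spectrum produces only that substitution type", {
  s <- setNames(rep(0, 12), names(default_spectrum()))
  s["G>A"] <- 1
  cfg <- tiny_cfg(seed = 13, spectrum = s, noise_fraction = 0,
                  n_background_variants = 0L)
  pop <- simulate_ems_population(make_genome(cfg), cfg)
  expect_gt(nrow(pop$truth$induced), 0L)
  expect_true(all(pop$truth$induced$ref == "G"))
  expect_true(all(pop$truth$induced$alt == "A"))
})

test_that("the whole module is deterministic given the seed", {
  cfg <- tiny_cfg(seed = 31)
  p1 <- simulate_ems_population(make_genome(cfg), cfg)
  p2 <- simulate_ems_population(make_genome(cfg), cfg)
  expect_identical(p1$truth$induced, p2$truth$induced)
  expect_identical(p1$samples$mut01$variants, p2$samples$mut01$variants)
})

test_that("induced Poisson mean tracks density times genome length", {
  # expectation check at moderate n: mean of 8 seeded replicates within
  # 4 SD of the Poisson mean
  cfg0 <- tiny_cfg()
  g <- make_genome(cfg0)
  lambda <- sum(g$chrom$length) / 500
  n <- vapply(1:8, function(s) {
    cfg <- tiny_cfg(seed = 100 + s, n_background_variants = 0L,
                    noise_fraction = 0, n_mutant_samples = 1L)
    nrow(simulate_ems_population(g, cfg)$truth$induced)
  }, numeric(1))
  expect_lt(abs(mean(n) - lambda), 4 * sqrt(lambda / 8))
})

test_that("files written by the simulator re-read with zero loss", {
  cfg <- tiny_cfg(seed = 41)
  g <- make_genome(cfg)
  dir <- withr::local_tempdir()
  pop <- simulate_ems_population(g, cfg, out_dir = dir)
  vs <- read_vcf(pop$paths$mut01, sample = "mut01")
  a <- pop$samples$mut01$variants
  b <- vs$variants
  expect_equal(b[order(b$chrom, b$pos, b$alt), ],
               a[order(a$chrom, a$pos, a$alt), ],
               ignore_attr = TRUE)
  fa <- file.path(dir, "ref.fa")
  write_genome_fasta(g, fa)
  expect_identical(as.character(read_genome_fasta(fa)$seq),
                   as.character(g$seq))
})

test_that("phenotype simulation respects degenerate parameters", {
  em <- default_effect_model()
  em$germination$prob <- 1
  em$pouch$root_sd <- 0
  em$pouch$shoot_sd <- 0
  pt <- simulate_phenotypes(n_lines = 20, effect_model = em, seed = 5,
                            n_tolerant = 3, pouch_n = 4)
  expect_true(all(pt$germination$seeds_germinated ==
                    pt$germination$seeds_sown))
  at50 <- pt$pouch[pt$pouch$concentration == 50 &
                     pt$pouch$group == "mutant", ]
  expect_true(all(at50$root_length == em$pouch$root_mean[1]))
  expect_error(
    simulate_phenotypes(20, within(em, germination$prob <- 1.2), seed = 1),
    "probabilities")
})

test_that("phenotype tables round-trip through TSV", {
  pt <- simulate_phenotypes(n_lines = 15, seed = 2, n_tolerant = 2,
                            pouch_n = 5, field_lines = 6)
  dir <- withr::local_tempdir()
  write_phenotypes(pt, dir)
  back <- read_phenotypes(dir)
  for (nm in c("germination", "pouch", "field")) {
    expect_equal(back[[nm]], pt[[nm]], ignore_attr = TRUE, tolerance = 1e-12)
  }
})
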