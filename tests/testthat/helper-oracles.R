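# Independent oracles and small builders shared across test files.

# Naive whole-CDS retranslation oracle: apply the substitution to the
# genome, re-extract and literally re-translate the entire spliced CDS
# (no initiator-codon special casing), and classify from the first amino
# acid difference.  Independent of the codon-coordinate arithmetic in
# classify_effect().
oracle_effect <- function(genome, genes, chrom, pos, alt, gene_id) {
  g2 <- genome
  g2$seq[[chrom]] <- Biostrings::replaceLetterAt(genome$seq[[chrom]],
                                                 pos, alt)
  aa0 <- as.character(Biostrings::translate(
    spliced_cds(genome, genes, gene_id), no.init.codon = TRUE))
  aa1 <- as.character(Biostrings::translate(
    spliced_cds(g2, genes, gene_id), no.init.codon = TRUE))
  if (aa0 == aa1) return("synonymous")
  d <- which(strsplit(aa0, "")[[1]] != strsplit(aa1, "")[[1]])[1]
  if (substr(aa1, d, d) == "*" && substr(aa0, d, d) != "*") "nonsense"
  else "non_synonymous"
}

# Textbook Welch t statistic from the group summaries.
welch_t_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# A hand-built single-gene genome: the CDS sequence `cds` is embedded in
# one chromosome with `pad` flanking bases; for minus-strand genes the
# reverse complement is written so the coding strand reads `cds`.
toy_gene_genome <- function(cds, strand = "+", pad = 6, chrom = "chr1A") {
  genomic <- if (strand == "+") cds else {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }
  seq <- paste0(strrep("T", pad), genomic, strrep("T", pad))
  genome <- ref_genome(Biostrings::DNAStringSet(setNames(seq, chrom)))
  genes <- data.frame(gene_id = "g1", chrom = chrom,
                      start = pad + 1L, end = pad + nchar(cds),
                      strand = strand, phase = 0L, exon = 1L,
                      stringsAsFactors = FALSE)
  list(genome = genome, genes = genes)
}

# variant_set from bare columns, defaulting to clean depth/quality
make_vs <- function(sample, chrom, pos, ref, alt, dp = 10L, qual = 50) {
  variant_set(sample, data.frame(chrom = chrom, pos = pos, ref = ref,
                                 alt = alt, dp = dp, qual = qual,
                                 stringsAsFactors = FALSE))
}

# small shared simulation (built once per test run)
tiny_cfg <- function(seed = 11, ...) {
  args <- list(seed = seed,
               chromosome_spec = data.frame(
                 name = c("chr1A", "chr1B", "chr1D"),
                 subgenome = c("A", "B", "D"),
                 length = c(30000L, 36000L, 24000L)),
               n_background_variants = 40L,
               n_genes = 0L,
               n_mutant_samples = 2L,
               mutation_density = 1 / 500)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
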