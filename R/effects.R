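#' Classify substitutions as synonymous, non-synonymous or nonsense
#'
#' Locates each substitution in the CDS gene models, reads off the affected
#' codon via cumulative CDS coordinates, substitutes the base on the coding
#' strand and translates both codons with the standard (plant nuclear)
#' genetic code.  For minus-strand genes the coding sequence is the
#' reverse complement of the genomic intervals, so a genomic G>A reads as
#' C>T on the coding strand.  Variants outside every CDS are `non_coding`.
#' A stop codon mutated to a sense codon is reported as `non_synonymous`
#' with `stop_lost = TRUE` (the three-way scheme has no stop-loss class).
#'
#' @param variants A [variant_set()] or data frame with columns `chrom`,
#'   `pos`, `ref`, `alt`.
#' @param genes Gene table in the [make_gene_models()] layout.
#' @param genome A [ref_genome()]; the base at each variant position must
#'   equal the variant's ref allele, otherwise a data-integrity error is
#'   raised.
#' @return Data frame of effect calls, one row per variant x overlapping
#'   gene (plus one `non_coding` row for variants in no gene): `chrom`,
#'   `pos`, `ref`, `alt`, `gene_id`, `effect`, `codon_before`,
#'   `codon_after`, `aa_before`, `aa_after`, `stop_lost`.
#' @examples
#' cfg <- sim_config(seed = 3, n_mutant_samples = 1, n_genes = 10)
#' g0 <- make_genome(cfg)
#' gm <- make_gene_models(g0, cfg$n_genes, seed = cfg$seed)
#' pop <- simulate_ems_population(gm$genome, cfg)
#' calls <- classify_effect(pop$truth$induced, gm$genes, gm$genome)
#' table(calls$effect)
#' @export
classify_effect <- function(variants, genes, genome) {
  stopifnot(inherits(genome, "ref_genome"))
  df <- if (inherits(variants, "variant_set")) variants$variants else
    as.data.frame(variants)
  if (nrow(df) == 0L) return(empty_effect_table())

  observed <- genome_base(genome, df$chrom, df$pos)
  bad <- observed != df$ref
  if (any(bad)) {
    i <- which(bad)[1]
    stop("reference mismatch at ", df$chrom[i], ":", df$pos[i],
         " (variant ref ", df$ref[i], ", genome has ", observed[i], ")")
  }

  if (nrow(genes) == 0L) {
    out <- data.frame(df[, c("chrom", "pos", "ref", "alt")],
                      gene_id = NA_character_, effect = "non_coding",
                      codon_before = NA_character_,
                      codon_after = NA_character_,
                      aa_before = NA_character_, aa_after = NA_character_,
                      stop_lost = FALSE, stringsAsFactors = FALSE)
    return(out)
  }

  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start,
                                                      genes$end))
  gr_var <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos,
                                                              df$pos))
  hits <- GenomicRanges::findOverlaps(gr_var, gr_genes)
  vi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)

  code <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  # per-gene spliced CDS and the cumulative length preceding each interval
  gene_ids <- unique(genes$gene_id)
  cds_cache <- lapply(setNames(gene_ids, gene_ids), function(id) {
    as.character(spliced_cds(genome, genes, id))
  })
  g_ord <- order(genes$gene_id, genes$exon)
  offset <- integer(nrow(genes))
  for (id in gene_ids) {
    sel <- g_ord[genes$gene_id[g_ord] == id]
    len <- genes$end[sel] - genes$start[sel] + 1L
    offset[sel] <- cumsum(c(0L, len[-length(len)]))
  }

  rows <- vector("list", length(vi))
  for (k in seq_along(vi)) {
    v <- df[vi[k], ]
    grow <- genes[gi[k], ]
    cds <- cds_cache[[grow$gene_id]]
    if (grow$strand == "+") {
      cds_pos <- offset[gi[k]] + (v$pos - grow$start) + 1L
      ref_c <- v$ref; alt_c <- v$alt
    } else {
      cds_pos <- offset[gi[k]] + (grow$end - v$pos) + 1L
      ref_c <- comp[[v$ref]]; alt_c <- comp[[v$alt]]
    }
    ci <- (cds_pos - 1L) %/% 3L + 1L
    within <- (cds_pos - 1L) %% 3L + 1L
    codon_before <- substr(cds, 3L * ci - 2L, 3L * ci)
    if (substr(codon_before, within, within) != ref_c) {
      stop("internal CDS coordinate mismatch in ", grow$gene_id, " at ",
           v$chrom, ":", v$pos)
    }
    codon_after <- codon_before
    substr(codon_after, within, within) <- alt_c
    aa_before <- code[[codon_before]]
    aa_after <- code[[codon_after]]
    effect <- if (aa_before == aa_after) "synonymous"
      else if (aa_after == "*") "nonsense"
      else "non_synonymous"
    rows[[k]] <- data.frame(
      chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      gene_id = grow$gene_id, effect = effect,
      codon_before = codon_before, codon_after = codon_after,
      aa_before = aa_before, aa_after = aa_after,
      stop_lost = aa_before == "*" && aa_after != "*",
      stringsAsFactors = FALSE
    )
  }
  coding <- if (length(rows) > 0L) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else NULL

  out_idx <- setdiff(seq_len(nrow(df)), unique(vi))
  noncoding <- if (length(out_idx) > 0L) {
    data.frame(df[out_idx, c("chrom", "pos", "ref", "alt")],
               gene_id = NA_character_, effect = "non_coding",
               codon_before = NA_character_, codon_after = NA_character_,
               aa_before = NA_character_, aa_after = NA_character_,
               stop_lost = FALSE, stringsAsFactors = FALSE)
  } else NULL
  out <- rbind(coding, noncoding)
  if (is.null(out)) out <- empty_effect_table()
  rownames(out) <- NULL
  out
}

empty_effect_table <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), gene_id = character(0),
             effect = character(0), codon_before = character(0),
             codon_after = character(0), aa_before = character(0),
             aa_after = character(0), stop_lost = logical(0),
             stringsAsFactors = FALSE)
}

#' Summarize effect-class fractions
#'
#' Fractions of synonymous / non-synonymous / nonsense calls are computed
#' over coding calls only; `non_coding` calls are excluded from the
#' three-way denominator and reported as a separate count.  When a variant
#' overlaps several genes its most severe call is used
#' (nonsense > non_synonymous > synonymous).  The non-synonymous to
#' synonymous ratio is a plain unitless ratio.
#'
#' @param calls Data frame from [classify_effect()]; must be non-empty.
#' @return List: `n_coding`, `n_non_coding`, `fractions` (named
#'   percentages, `NA` when there are no coding calls), `nonsyn_syn_ratio`.
#' @examples
#' calls <- data.frame(chrom = "c", pos = 1:4, ref = "G", alt = "A",
#'                     gene_id = "g",
#'                     effect = c("synonymous", "synonymous",
#'                                "non_synonymous", "nonsense"))
#' effect_fractions(calls)$fractions  # 50 / 25 / 25
#' @export
effect_fractions <- function(calls) {
  if (nrow(calls) == 0L) stop("no effect calls supplied")
  severity <- c(nonsense = 3L, non_synonymous = 2L, synonymous = 1L,
                non_coding = 0L)
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  sev <- severity[calls$effect]
  best <- tapply(sev, key, max)
  effects <- names(severity)[match(as.integer(best), severity)]
  n_non_coding <- sum(effects == "non_coding")
  coding <- effects[effects != "non_coding"]
  n_coding <- length(coding)
  if (n_coding == 0L) {
    return(list(n_coding = 0L, n_non_coding = n_non_coding,
                fractions = c(synonymous = NA_real_,
                              non_synonymous = NA_real_,
                              nonsense = NA_real_),
                nonsyn_syn_ratio = NA_real_))
  }
  cnt <- table(factor(coding, levels = c("synonymous", "non_synonymous",
                                         "nonsense")))
  fractions <- 100 * as.numeric(cnt) / n_coding
  names(fractions) <- names(cnt)
  ratio <- if (cnt[["synonymous"]] > 0) {
    cnt[["non_synonymous"]] / cnt[["synonymous"]]
  } else NA_real_
  list(n_coding = n_coding, n_non_coding = n_non_coding,
       fractions = fractions, nonsyn_syn_ratio = ratio)
}
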