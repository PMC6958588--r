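#' Simulate CDS gene models
#'
#' Plants `n_genes` non-overlapping protein-coding genes in the genome and
#' returns both the gene table and the updated genome.  Each gene is a CDS
#' of 1-3 exons on a random strand whose spliced coding sequence starts with
#' ATG, ends with a single stop codon and contains no internal stop; the
#' coding sequence is written into the reference so that the gene models and
#' the genome are mutually consistent (random sequence almost never hosts
#' long open reading frames, so the generator edits the reference rather
#' than searching it).
#'
#' @param genome A [ref_genome()].
#' @param n_genes Number of genes to place (>= 0).
#' @param seed Integer seed.
#' @param codon_range Range of internal codons per gene (excluding the ATG
#'   and the stop), default 10-100.
#' @param max_exons Maximum exons per gene (default 3).
#' @param max_tries Placement retries per gene before giving up.
#' @return A list with `genes` (data frame: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `phase`, `exon` — one row per CDS interval, 1-based
#'   closed, sorted by position within gene) and `genome` (the edited
#'   [ref_genome()]).
#' @examples
#' g <- make_genome(sim_config(seed = 1))
#' gm <- make_gene_models(g, n_genes = 5, seed = 2)
#' nrow(gm$genes) >= 5
#' @export
make_gene_models <- function(genome, n_genes, seed,
                             codon_range = c(10L, 100L),
                             max_exons = 3L, max_tries = 200L) {
  stopifnot(inherits(genome, "ref_genome"), n_genes >= 0)
  if (n_genes == 0L) {
    return(list(genes = empty_gene_table(), genome = genome))
  }
  set.seed(seed)
  chrom_tab <- genome$chrom
  stop_codons <- c("TAA", "TAG", "TGA")
  sense_codons <- setdiff(names(Biostrings::GENETIC_CODE), stop_codons)

  occupied <- lapply(chrom_tab$name, function(x) {
    matrix(numeric(0), ncol = 2)
  })
  names(occupied) <- chrom_tab$name

  rows <- list()
  edits <- list()  # per chromosome: list of (at = IRanges, value = chars)

  for (gi in seq_len(n_genes)) {
    n_codon <- sample(seq(codon_range[1], codon_range[2]), 1L)
    cds <- paste0("ATG",
                  paste(sample(sense_codons, n_codon, replace = TRUE),
                        collapse = ""),
                  sample(stop_codons, 1L))
    cds_len <- nchar(cds)
    n_exon <- sample(seq_len(max_exons), 1L)
    # split the coding sequence into n_exon chunks of >= 3 bases
    if (n_exon > 1L) {
      cuts <- sort(sample(seq(3L, cds_len - 3L), n_exon - 1L))
      while (any(diff(c(0L, cuts, cds_len)) < 3L)) {
        cuts <- sort(sample(seq(3L, cds_len - 3L), n_exon - 1L))
      }
    } else {
      cuts <- integer(0)
    }
    chunk_len <- diff(c(0L, cuts, cds_len))
    introns <- if (n_exon > 1L) {
      sample(20:100, n_exon - 1L, replace = TRUE)
    } else integer(0)
    span <- sum(chunk_len) + sum(introns)
    strand <- sample(c("+", "-"), 1L)

    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ci <- sample(nrow(chrom_tab), 1L, prob = chrom_tab$length)
      clen <- chrom_tab$length[ci]
      if (clen < span + 2L) next
      start <- sample(clen - span + 1L, 1L)
      end <- start + span - 1L
      occ <- occupied[[chrom_tab$name[ci]]]
      if (nrow(occ) > 0 && any(start <= occ[, 2] & end >= occ[, 1])) next
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place gene ", gi, " without overlap after ",
           max_tries, " tries; enlarge the genome or reduce n_genes")
    }
    chrom <- chrom_tab$name[ci]
    occupied[[chrom]] <- rbind(occupied[[chrom]], c(start, end))

    # coding-order rank of each genomic exon (left to right): leftmost chunk
    # first on +, rightmost first on -
    rank_coding <- if (strand == "+") seq_len(n_exon) else rev(seq_len(n_exon))
    glen <- chunk_len[rank_coding]       # genomic exon lengths, left to right
    exon_starts <- start + cumsum(c(0L, glen[-n_exon] + introns))
    exon_ends <- exon_starts + glen - 1L
    # phase = bases to skip at the feature's 5' end to reach a codon start
    cum_before <- cumsum(c(0L, chunk_len))[rank_coding]
    phase <- (3L - (cum_before %% 3L)) %% 3L

    # write coding chunks into the genome
    chunk_start <- cumsum(c(1L, chunk_len[-n_exon]))
    chunk_seq <- substring(cds, chunk_start, cumsum(chunk_len))
    for (k in seq_len(n_exon)) {
      value <- chunk_seq[rank_coding[k]]
      if (strand == "-") {
        value <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(value)))
      }
      edits[[chrom]] <- c(edits[[chrom]],
                          list(list(start = exon_starts[k],
                                    end = exon_ends[k], value = value)))
    }

    rows[[gi]] <- data.frame(
      gene_id = sprintf("gene%03d", gi),
      chrom = chrom,
      start = exon_starts,
      end = exon_ends,
      strand = strand,
      phase = phase,
      exon = rank_coding,
      stringsAsFactors = FALSE
    )
  }

  seq <- genome$seq
  for (chrom in names(edits)) {
    ed <- edits[[chrom]]
    at <- IRanges::IRanges(vapply(ed, `[[`, numeric(1), "start"),
                           vapply(ed, `[[`, numeric(1), "end"))
    seq[[chrom]] <- Biostrings::replaceAt(
      seq[[chrom]], at, as(vapply(ed, `[[`, character(1), "value"),
                           "DNAStringSet"))
  }
  genes <- do.call(rbind, rows)
  rownames(genes) <- NULL
  validate_gene_models(genes)
  list(genes = genes,
       genome = ref_genome(seq, subgenome = genome$chrom$subgenome))
}

empty_gene_table <- function() {
  data.frame(gene_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             phase = integer(0), exon = integer(0), stringsAsFactors = FALSE)
}

# structural checks shared by the simulator and the GFF3 reader
validate_gene_models <- function(genes) {
  if (nrow(genes) == 0L) return(invisible(genes))
  stopifnot(all(genes$strand %in% c("+", "-")),
            all(genes$start <= genes$end))
  for (gid in unique(genes$gene_id)) {
    g <- genes[genes$gene_id == gid, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1L && any(g$start[-1] <= g$end[-nrow(g)])) {
      stop("overlapping CDS intervals within ", gid)
    }
    if (sum(g$end - g$start + 1L) %% 3L != 0L) {
      stop("spliced CDS length of ", gid, " not divisible by 3")
    }
  }
  invisible(genes)
}

#' Extract the spliced coding sequence of one gene
#'
#' Concatenates the CDS intervals in genomic order and, for minus-strand
#' genes, reverse-complements the result, so the returned sequence always
#' reads 5'->3' on the coding strand.
#'
#' @param genome A [ref_genome()].
#' @param genes Gene table as returned by [make_gene_models()].
#' @param gene_id Gene identifier.
#' @return A `DNAString` with the spliced CDS.
#' @export
spliced_cds <- function(genome, genes, gene_id) {
  g <- genes[genes$gene_id == gene_id, ]
  if (nrow(g) == 0L) stop("unknown gene_id: ", gene_id)
  g <- g[order(g$start), ]
  chrom <- g$chrom[1]
  parts <- Biostrings::extractAt(genome$seq[[chrom]],
                                 IRanges::IRanges(g$start, g$end))
  cds <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
  if (g$strand[1] == "-") cds <- Biostrings::reverseComplement(cds)
  cds
}

#' Write gene models as GFF3
#'
#' Emits one CDS feature per interval (1-based closed coordinates, strand
#' and phase columns, `ID`/`Parent` attributes per gene).
#'
#' @param genes Gene table ([make_gene_models()] layout).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand
  )
  gr$source <- "emschar"
  gr$type <- "CDS"
  gr$phase <- as.integer(genes$phase)
  gr$ID <- sprintf("%s.cds%d", genes$gene_id, genes$exon)
  gr$Parent <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read CDS gene models from GFF3
#'
#' Keeps CDS features only; the gene identifier is taken from the `Parent`
#' attribute (falling back to `ID` with a trailing `.cds<k>` stripped).
#'
#' @param path GFF3 file.
#' @return Gene table in the [make_gene_models()] layout.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) return(empty_gene_table())
  parent <- as.character(gr$Parent)
  parent[is.na(parent) | parent == "character(0)"] <- NA_character_
  id_fallback <- sub("\\.cds\\d+$", "", as.character(gr$ID))
  gene_id <- ifelse(is.na(parent), id_fallback, parent)
  genes <- data.frame(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    phase = as.integer(gr$phase),
    stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$gene_id, genes$start), ]
  # exon rank in coding order
  genes$exon <- unlist(lapply(split(genes, genes$gene_id), function(g) {
    if (g$strand[1] == "+") seq_len(nrow(g)) else rev(seq_len(nrow(g)))
  }), use.names = FALSE)
  rownames(genes) <- NULL
  validate_gene_models(genes)
  genes
}
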