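#' Reference genome container
#'
#' A thin wrapper around a [Biostrings::DNAStringSet] that carries the
#' sub-genome label of each chromosome.  All mutation-density computations
#' use its chromosome lengths as denominators.
#'
#' @param seq A named `DNAStringSet` (names = chromosome names).
#' @param subgenome Character vector of sub-genome labels, one per
#'   chromosome (`NA` for unplaced chromosomes); if omitted, labels are
#'   parsed from the trailing letter of each chromosome name via
#'   [parse_subgenome()].
#' @param subgenome_labels Declared label set used when parsing.
#' @return An object of class `ref_genome` with elements `seq` and `chrom`
#'   (data frame: `name`, `subgenome`, `length`).
#' @export
ref_genome <- function(seq, subgenome = NULL,
                       subgenome_labels = c("A", "B", "D")) {
  if (!methods::is(seq, "DNAStringSet")) {
    seq <- Biostrings::DNAStringSet(seq)
  }
  if (is.null(names(seq))) stop("chromosome sequences must be named")
  if (is.null(subgenome)) {
    subgenome <- parse_subgenome(names(seq), labels = subgenome_labels)
  }
  chrom <- data.frame(name = names(seq),
                      subgenome = subgenome,
                      length = Biostrings::width(seq),
                      stringsAsFactors = FALSE)
  structure(list(seq = seq, chrom = chrom), class = "ref_genome")
}

#' Parse sub-genome labels from chromosome names
#'
#' The wheat convention encodes the ancestral sub-genome as the trailing
#' letter of the chromosome label (`"chr5B"` -> `"B"`).  Names whose
#' trailing letter is not in `labels` (e.g. `"chrUn"`) get `NA`: they count
#' toward genome-wide rates but no sub-genome stratum.
#'
#' @param names Character vector of chromosome names.
#' @param pattern Regex with one capture group extracting the label.
#' @param labels Declared label set.
#' @return Character vector of labels or `NA`.
#' @examples
#' parse_subgenome(c("chr1A", "chr3B", "chrUn"))
#' @export
parse_subgenome <- function(names, pattern = "([A-Za-z])$",
                            labels = c("A", "B", "D")) {
  m <- regmatches(names, regexec(pattern, names))
  lab <- vapply(m, function(x) if (length(x) >= 2) x[2] else NA_character_,
                character(1))
  lab[!(lab %in% labels)] <- NA_character_
  lab
}

#' Simulate a toy reference genome
#'
#' Draws i.i.d. uniform A/C/G/T sequence for every chromosome in the
#' configuration.  Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [ref_genome()].
#' @examples
#' g <- make_genome(sim_config(seed = 1))
#' sum(g$chrom$length)
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$chromosome_spec
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(spec$length, function(n) {
    paste(sample(bases, n, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- spec$name
  ref_genome(Biostrings::DNAStringSet(seqs),
             subgenome = spec$subgenome,
             subgenome_labels = config$subgenome_labels)
}

#' Write a reference genome as FASTA
#'
#' @param genome A [ref_genome()].
#' @param path Output file; sequence lines wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "ref_genome"))
  Biostrings::writeXStringSet(genome$seq, filepath = path, width = 60L)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @inheritParams ref_genome
#' @return A [ref_genome()].
#' @export
read_genome_fasta <- function(path, subgenome_labels = c("A", "B", "D")) {
  seq <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry a description after the first whitespace
  names(seq) <- sub("\\s.*$", "", names(seq))
  ref_genome(seq, subgenome_labels = subgenome_labels)
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("Reference genome:", nrow(x$chrom), "chromosomes,",
      format(sum(x$chrom$length), big.mark = ","), "bases\n")
  sg <- subgenome_lengths(x)
  for (i in seq_len(nrow(sg))) {
    cat(sprintf("  sub-genome %s: %s bases\n", sg$subgenome[i],
                format(sg$length[i], big.mark = ",")))
  }
  invisible(x)
}

#' Total length per sub-genome
#'
#' @param genome A [ref_genome()].
#' @return Data frame `subgenome`, `length` (labelled sub-genomes only).
#' @export
subgenome_lengths <- function(genome) {
  stopifnot(inherits(genome, "ref_genome"))
  keep <- !is.na(genome$chrom$subgenome)
  agg <- stats::aggregate(length ~ subgenome, data = genome$chrom[keep, ],
                          FUN = sum)
  agg[order(agg$subgenome), , drop = FALSE]
}

# Base at 1-based position(s) on one chromosome; used for ref checks and
# codon extraction.
genome_base <- function(genome, chrom, pos) {
  idx <- match(chrom, names(genome$seq))
  if (anyNA(idx)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(idx)]), collapse = ", "))
  }
  out <- character(length(pos))
  for (i in unique(idx)) {
    sel <- which(idx == i)
    frag <- Biostrings::extractAt(genome$seq[[i]],
                                  IRanges::IRanges(pos[sel], pos[sel]))
    out[sel] <- as.character(frag)
  }
  out
}
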