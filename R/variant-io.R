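#' Variant set container
#'
#' A sample's biallelic single-base substitutions plus a provenance ledger
#' recording what happened to every record that was ever parsed, so that
#' nothing is silently dropped.  The conservation identity
#' `retained + filtered + rejected = parsed` holds at all times (`parsed`
#' counts allele-level candidates after multi-allelic decomposition).
#'
#' @param sample Sample identifier.
#' @param variants Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single bases), `dp` (read depth), `qual`.
#' @param provenance Named integer vector; missing entries default to a
#'   ledger describing `variants` as fully retained.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(sample, variants, provenance = NULL) {
  need <- c("chrom", "pos", "ref", "alt", "dp", "qual")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols) > 0L) {
    stop("variants lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  variants <- as.data.frame(variants)[need]
  if (nrow(variants) > 0L) {
    stopifnot(all(variants$pos >= 1L), all(variants$dp >= 0L),
              all(variants$ref != variants$alt),
              all(nchar(variants$ref) == 1L), all(nchar(variants$alt) == 1L))
  }
  key <- variant_key(variants)
  if (anyDuplicated(key)) {
    stop("duplicated (chrom, pos, ref, alt) keys in sample ", sample)
  }
  if (is.null(provenance)) {
    provenance <- c(records = nrow(variants), parsed = nrow(variants),
                    retained = nrow(variants), rejected_indel = 0L,
                    rejected_ambiguous = 0L, multiallelic_records = 0L,
                    filtered = 0L, subtracted = 0L)
  }
  structure(list(sample = sample, variants = variants,
                 provenance = provenance),
            class = "variant_set")
}

variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("Variant set '", x$sample, "': ", nrow(x$variants),
      " substitutions\n", sep = "")
  p <- x$provenance
  cat("  provenance:", paste(names(p), p, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of variants in a set
#' @param vs A [variant_set()].
#' @return Integer count.
#' @export
n_variants <- function(vs) nrow(vs$variants)

#' Read a VCF file into a variant set
#'
#' Parses a VCF (v4.2) via \pkg{vcfR}.  Biallelic single-base substitutions
#' become variants; multi-allelic sites are decomposed into one candidate
#' per alternate allele (and counted in provenance); indels and records
#' with ambiguous bases are routed to the rejected counts, never silently
#' dropped.  Site depth is taken from the INFO `DP` field ("total depth");
#' records without it get depth 0.
#'
#' @param path VCF file.
#' @param sample Sample identifier; defaults to the file name without
#'   extension.
#' @return A [variant_set()].
#' @export
read_vcf <- function(path, sample = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample)) sample <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  if (n_rec == 0L) {
    empty <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        dp = integer(0), qual = numeric(0),
                        stringsAsFactors = FALSE)
    return(variant_set(sample, empty))
  }
  alt_list <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  multiallelic <- sum(n_alt > 1L)
  rec_idx <- rep(seq_len(n_rec), n_alt)
  dp <- suppressWarnings(as.integer(sub(".*DP=([0-9]+).*", "\\1",
                                        fix$INFO)))
  dp[is.na(dp) | !grepl("DP=", fix$INFO)] <- 0L
  cand <- data.frame(
    chrom = fix$CHROM[rec_idx],
    pos = as.integer(fix$POS[rec_idx]),
    ref = toupper(fix$REF[rec_idx]),
    alt = toupper(unlist(alt_list)),
    dp = dp[rec_idx],
    qual = suppressWarnings(as.numeric(fix$QUAL[rec_idx])),
    stringsAsFactors = FALSE
  )
  cand$qual[is.na(cand$qual)] <- 0
  is_indel <- nchar(cand$ref) != 1L | nchar(cand$alt) != 1L |
    cand$alt %in% c("*", "<DEL>", "<INS>", "<NON_REF>")
  acgt <- c("A", "C", "G", "T")
  is_ambiguous <- !is_indel &
    (!(cand$ref %in% acgt) | !(cand$alt %in% acgt) | cand$ref == cand$alt)
  keep <- !is_indel & !is_ambiguous
  variants <- cand[keep, , drop = FALSE]
  variants <- variants[!duplicated(variant_key(variants)), , drop = FALSE]
  rownames(variants) <- NULL
  provenance <- c(records = n_rec,
                  parsed = nrow(cand),
                  retained = nrow(variants),
                  rejected_indel = sum(is_indel),
                  rejected_ambiguous = sum(is_ambiguous) +
                    (sum(keep) - nrow(variants)),  # duplicate keys
                  multiallelic_records = multiallelic,
                  filtered = 0L, subtracted = 0L)
  variant_set(sample, variants, provenance)
}

#' Write a variant set as VCF v4.2
#'
#' @param vs A [variant_set()].
#' @param genome Optional [ref_genome()]; when given, `##contig` header
#'   lines are emitted and records are sorted in genome chromosome order.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(vs, genome = NULL, path) {
  stopifnot(inherits(vs, "variant_set"))
  df <- vs$variants
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=emschar %s", as.character(utils::packageVersion("emschar"))),
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">'
  )
  if (!is.null(genome)) {
    header <- c(header,
                sprintf("##contig=<ID=%s,length=%d>", genome$chrom$name,
                        genome$chrom$length))
    df <- sort_variants(df, genome)
  } else {
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
  }
  header <- c(header,
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\tDP=%d",
                  df$chrom, df$pos, df$ref, df$alt,
                  format(df$qual, trim = TRUE), df$dp)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a variant set as TSV
#'
#' @param vs A [variant_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(vs, path) {
  write.table(cbind(sample = vs$sample, vs$variants), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply the depth/quality filters
#'
#' Retains exactly the records with `dp > min_depth_exclusive` *and*
#' `qual > min_qual_exclusive` — both strict inequalities, so the default
#' keeps `DP > 5` and `QUAL > 20`, the filtering applied to the SAMtools
#' and FreeBayes call sets before any downstream analysis.
#'
#' @param vs A [variant_set()].
#' @param min_depth_exclusive Depth threshold (exclusive), default 5.
#' @param min_qual_exclusive Quality threshold (exclusive), default 20.
#' @return A filtered [variant_set()]; the number of removed records is
#'   added to the `filtered` provenance count.
#' @examples
#' df <- data.frame(chrom = "chr1A", pos = 1:2, ref = "G", alt = "A",
#'                  dp = c(5L, 6L), qual = c(50, 21))
#' n_variants(apply_filters(variant_set("s", df)))  # 1: DP=5 is removed
#' @export
apply_filters <- function(vs, min_depth_exclusive = 5,
                          min_qual_exclusive = 20) {
  stopifnot(inherits(vs, "variant_set"),
            min_depth_exclusive >= 0, min_qual_exclusive >= 0)
  keep <- vs$variants$dp > min_depth_exclusive &
    vs$variants$qual > min_qual_exclusive
  out <- vs
  out$variants <- vs$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$provenance["filtered"] <- out$provenance["filtered"] + sum(!keep)
  out$provenance["retained"] <- nrow(out$variants)
  out
}

#' Subtract variants shared with the unmutagenized control
#'
#' Removes from the mutant set every variant whose full
#' `(chrom, pos, ref, alt)` key also occurs in the control set, so that the
#' remaining variants can be attributed to mutagenesis rather than to
#' pre-existing divergence between the parent line and the reference
#' assembly.  Matching on position only (any allele) is available via
#' `match_on`.
#'
#' @param mutant,control [variant_set()]s filtered with the same
#'   thresholds.
#' @param match_on `"key"` (default, full-key matching) or `"position"`.
#' @return The mutant [variant_set()] minus shared variants; removals are
#'   counted in the `subtracted` provenance entry.
#' @examples
#' m <- variant_set("m", data.frame(chrom = "chr1A", pos = c(100L, 200L),
#'                                  ref = c("G", "C"), alt = c("A", "T"),
#'                                  dp = 10L, qual = 50))
#' c0 <- variant_set("c", data.frame(chrom = "chr1A", pos = 200L,
#'                                   ref = "C", alt = "T", dp = 10L,
#'                                   qual = 50))
#' subtract_control(m, c0)$variants$pos  # 100
#' @export
subtract_control <- function(mutant, control, match_on = c("key", "position")) {
  stopifnot(inherits(mutant, "variant_set"), inherits(control, "variant_set"))
  match_on <- match.arg(match_on)
  if (identical(mutant$sample, control$sample)) {
    stop("mutant and control have the same sample identifier ('",
         mutant$sample, "'): refusing to subtract a set from itself")
  }
  if (match_on == "key") {
    mk <- variant_key(mutant$variants)
    ck <- variant_key(control$variants)
  } else {
    mk <- paste(mutant$variants$chrom, mutant$variants$pos, sep = ":")
    ck <- paste(control$variants$chrom, control$variants$pos, sep = ":")
  }
  shared <- mk %in% ck
  out <- mutant
  out$variants <- mutant$variants[!shared, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$provenance["subtracted"] <- out$provenance["subtracted"] + sum(shared)
  out$provenance["retained"] <- nrow(out$variants)
  out
}
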