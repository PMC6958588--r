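#' Aggregate the 12-type substitution spectrum
#'
#' Tallies every variant into one of the twelve base-to-base conversion
#' types and rolls the counts up from chromosome to sub-genome to genome.
#' Shares are computed over classified substitutions:
#' `transition_share + transversion_share = 100` exactly, and the
#' EMS-canonical share (G>A plus C>T) is the fraction of changes carrying
#' the expected mutagenesis signature.
#'
#' @param vs A [variant_set()] or a data frame with columns `chrom`, `ref`,
#'   `alt`.
#' @param genome A [ref_genome()]; every variant chromosome must exist in
#'   it.
#' @return An object of class `spectrum_report` with elements `counts`
#'   (long data frame: `level`, `stratum`, `type`, `count`, zero-filled
#'   over all 12 types) and `summary` (per stratum: totals, transition /
#'   transversion / EMS-canonical counts and percentage shares, one
#'   decimal precision carried in full and rounded only for display).
#' @examples
#' cfg <- sim_config(seed = 1, n_mutant_samples = 1)
#' g <- make_genome(cfg)
#' pop <- simulate_ems_population(g, cfg)
#' rep <- aggregate_spectrum(pop$samples$mut01, g)
#' rep$summary[rep$summary$level == "genome", ]
#' @export
aggregate_spectrum <- function(vs, genome) {
  stopifnot(inherits(genome, "ref_genome"))
  df <- if (inherits(vs, "variant_set")) vs$variants else as.data.frame(vs)
  unknown <- setdiff(unique(df$chrom), genome$chrom$name)
  if (length(unknown) > 0L) {
    stop("variant chromosome(s) not in the genome: ",
         paste(unknown, collapse = ", "))
  }
  types <- substitution_types()
  cls <- if (nrow(df) > 0L) classify_substitution(df$ref, df$alt) else types[0, ]

  strata <- stratum_table(genome)
  chrom_of <- df$chrom
  sg_of <- genome$chrom$subgenome[match(chrom_of, genome$chrom$name)]

  tally <- function(level, stratum_names, member) {
    do.call(rbind, lapply(stratum_names, function(s) {
      sel <- member == s & !is.na(member)
      cnt <- table(factor(cls$type[sel], levels = types$type))
      data.frame(level = level, stratum = s, type = types$type,
                 count = as.integer(cnt), stringsAsFactors = FALSE)
    }))
  }
  counts <- rbind(
    tally("genome", "genome", rep("genome", nrow(df))),
    tally("subgenome", strata$subgenome, sg_of),
    tally("chromosome", strata$chromosome, chrom_of)
  )
  rownames(counts) <- NULL

  summ <- do.call(rbind, lapply(split(counts, paste(counts$level,
                                                    counts$stratum)), {
    function(x) {
      m <- match(x$type, types$type)
      total <- sum(x$count)
      ts <- sum(x$count[types$klass[m] == "transition"])
      tv <- total - ts
      ems <- sum(x$count[types$ems_canonical[m]])
      data.frame(level = x$level[1], stratum = x$stratum[1],
                 total = total, transitions = ts, transversions = tv,
                 ems_canonical = ems,
                 transition_share = if (total > 0) 100 * ts / total else NA,
                 transversion_share = if (total > 0) 100 * tv / total else NA,
                 ems_canonical_share = if (total > 0) 100 * ems / total else NA,
                 stringsAsFactors = FALSE)
    }
  }))
  lvl_ord <- c(genome = 1L, subgenome = 2L, chromosome = 3L)
  summ <- summ[order(lvl_ord[summ$level], summ$stratum), ]
  rownames(summ) <- NULL
  structure(list(counts = counts, summary = summ), class = "spectrum_report")
}

stratum_table <- function(genome) {
  list(chromosome = genome$chrom$name,
       subgenome = sort(unique(genome$chrom$subgenome[
         !is.na(genome$chrom$subgenome)])))
}

#' @export
print.spectrum_report <- function(x, ...) {
  g <- x$summary[x$summary$level == "genome", ]
  cat("Substitution spectrum:", g$total, "classified substitutions\n")
  cat(sprintf("  transitions %.1f%%, transversions %.1f%%, EMS-canonical (G>A + C>T) %.1f%%\n",
              g$transition_share, g$transversion_share,
              g$ems_canonical_share))
  top <- x$counts[x$counts$level == "genome", ]
  top <- top[order(-top$count), ][1:4, ]
  cat("  most frequent:",
      paste(sprintf("%s (%d)", top$type, top$count), collapse = ", "), "\n")
  invisible(x)
}

#' Mutation density per stratum
#'
#' Reports, genome-wide and per sub-genome and chromosome, the stratum
#' length divided by the number of variants observed in it — the "one
#' change per N bases" convention.  Strata with zero variants get `NA`
#' rather than an infinite density.  The denominator is always the
#' supplied reference's actual chromosome lengths; chromosomes without a
#' sub-genome label count toward the genome-wide rate only.
#'
#' @param vs A [variant_set()] or data frame with `chrom`.
#' @param genome A [ref_genome()].
#' @return Data frame of class `rate_report`: `level`, `stratum`,
#'   `length`, `count`, `bases_per_mutation`.
#' @examples
#' # 5 variants on a 100 kb genome -> one change per 20,000 bases
#' @export
mutation_rate <- function(vs, genome) {
  stopifnot(inherits(genome, "ref_genome"))
  df <- if (inherits(vs, "variant_set")) vs$variants else as.data.frame(vs)
  unknown <- setdiff(unique(df$chrom), genome$chrom$name)
  if (length(unknown) > 0L) {
    stop("variant chromosome(s) not in the genome: ",
         paste(unknown, collapse = ", "))
  }
  if (any(genome$chrom$length <= 0)) stop("zero-length stratum in genome")
  sg <- subgenome_lengths(genome)
  sg_of <- genome$chrom$subgenome[match(df$chrom, genome$chrom$name)]
  rows <- rbind(
    data.frame(level = "genome", stratum = "genome",
               length = sum(genome$chrom$length), count = nrow(df),
               stringsAsFactors = FALSE),
    data.frame(level = "subgenome", stratum = sg$subgenome,
               length = sg$length,
               count = vapply(sg$subgenome,
                              function(s) sum(sg_of == s, na.rm = TRUE),
                              integer(1)),
               stringsAsFactors = FALSE),
    data.frame(level = "chromosome", stratum = genome$chrom$name,
               length = genome$chrom$length,
               count = vapply(genome$chrom$name,
                              function(s) sum(df$chrom == s), integer(1)),
               stringsAsFactors = FALSE)
  )
  rows$bases_per_mutation <- ifelse(rows$count > 0,
                                    rows$length / rows$count, NA_real_)
  rownames(rows) <- NULL
  class(rows) <- c("rate_report", class(rows))
  rows
}

#' Rank chromosomes by substitution count
#'
#' @param report A `spectrum_report` from [aggregate_spectrum()].
#' @return Data frame `chromosome`, `count`, sorted by descending count;
#'   ties broken by chromosome name ascending.
#' @export
rank_chromosomes <- function(report) {
  stopifnot(inherits(report, "spectrum_report"))
  x <- report$counts[report$counts$level == "chromosome", ]
  if (nrow(x) == 0L) stop("report contains no chromosome strata")
  agg <- stats::aggregate(count ~ stratum, data = x, FUN = sum)
  agg <- agg[order(-agg$count, agg$stratum), ]
  out <- data.frame(chromosome = agg$stratum, count = agg$count,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Expand per-type counts into a synthetic variant table
#'
#' Turns a 12-type count table (e.g. [ems_reference_counts()]) into one
#' variant row per counted substitution, all on one chromosome, so that
#' printed spectra can be pushed through [aggregate_spectrum()] as a worked
#' example.  Positions are sequential and carry no meaning.
#'
#' @param counts Data frame with columns `ref`, `alt`, `count`.
#' @param chrom Chromosome name to place the synthetic variants on.
#' @return Data frame `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' x <- expand_type_counts(ems_reference_counts("OA70", "FreeBayes"))
#' nrow(x)  # 746904
#' @export
expand_type_counts <- function(counts, chrom = "chr1A") {
  idx <- rep(seq_len(nrow(counts)), counts$count)
  data.frame(chrom = chrom, pos = seq_along(idx),
             ref = counts$ref[idx], alt = counts$alt[idx],
             stringsAsFactors = FALSE)
}
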