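#' The twelve single-base substitution types
#'
#' Enumerates all ordered base-to-base conversions over \{A,C,G,T\}, read off
#' the reference strand (so G>A and C>T are distinct categories, even though
#' they describe the same event on complementary strands).  A substitution is
#' a transition when it stays within the purines (A<->G) or within the
#' pyrimidines (C<->T), a transversion otherwise.  G>A and C>T are flagged as
#' EMS-canonical: alkylation of guanine by ethyl methanesulfonate mispairs
#' O6-ethylguanine with T, fixing G:C -> A:T changes, which appear as G>A or
#' C>T depending on which strand carried the alkylated guanine.
#'
#' @return A 12-row data frame with columns `type` (e.g. `"G>A"`), `ref`,
#'   `alt`, `klass` (`"transition"` or `"transversion"`) and `ems_canonical`
#'   (logical).
#' @examples
#' substitution_types()
#' @export
substitution_types <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(ref = bases, alt = bases,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  purine <- c("A", "G")
  transition <- (grid$ref %in% purine) == (grid$alt %in% purine)
  type <- paste0(grid$ref, ">", grid$alt)
  out <- data.frame(
    type = type,
    ref = grid$ref,
    alt = grid$alt,
    klass = ifelse(transition, "transition", "transversion"),
    ems_canonical = type %in% c("G>A", "C>T"),
    stringsAsFactors = FALSE
  )
  # fixed presentation order: transitions first, EMS-canonical on top
  ord <- c("G>A", "C>T", "T>C", "A>G",
           "C>A", "G>T", "A>C", "T>G", "G>C", "C>G", "T>A", "A>T")
  out <- out[match(ord, out$type), ]
  rownames(out) <- NULL
  out
}

#' Classify a single-base substitution
#'
#' @param ref,alt Single bases in \{A,C,G,T\}; vectors are classified
#'   elementwise and recycled to a common length.
#' @return A data frame with one row per input: `type`, `ref`, `alt`,
#'   `klass`, `ems_canonical`.
#' @examples
#' classify_substitution("G", "A")   # transition, EMS-canonical
#' classify_substitution("T", "A")   # transversion
#' @export
classify_substitution <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- toupper(rep_len(as.character(ref), n))
  alt <- toupper(rep_len(as.character(alt), n))
  bad <- !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    stop("ref/alt must be single bases in {A,C,G,T}; offending pair(s): ",
         paste(unique(paste0(ref[bad], ">", alt[bad])), collapse = ", "))
  }
  if (any(ref == alt)) {
    stop("ref and alt must differ (got ",
         paste(unique(ref[ref == alt]), collapse = ", "), ")")
  }
  types <- substitution_types()
  idx <- match(paste0(ref, ">", alt), types$type)
  out <- types[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reference substitution-type counts for the two sequenced mutant lines
#'
#' Published per-type counts of EMS-induced SNPs for the salt-tolerant wheat
#' lines OA70 and OA42, as produced by two variant callers (SAMtools and
#' FreeBayes) after depth/quality filtering and subtraction of variants
#' shared with the unmutagenized BARI Gom-25 parent.  These counts are the
#' default substitution spectrum of the simulator and the worked example for
#' the spectrum aggregator.
#'
#' @param line `"OA70"` or `"OA42"`.
#' @param caller `"FreeBayes"` or `"SAMtools"`.
#' @return A 12-row data frame: `type`, `ref`, `alt`, `klass`,
#'   `ems_canonical`, `count`.
#' @examples
#' x <- ems_reference_counts("OA70", "FreeBayes")
#' sum(x$count)                          # 746904 classified substitutions
#' @export
ems_reference_counts <- function(line = c("OA70", "OA42"),
                                 caller = c("FreeBayes", "SAMtools")) {
  line <- match.arg(line)
  caller <- match.arg(caller)
  counts <- list(
    OA70 = list(
      SAMtools = c(219110, 227802, 46420, 46417,
                   12932, 12991, 10707, 10612, 10160, 10053, 7681, 7570),
      FreeBayes = c(220536, 227030, 81548, 83720,
                    19003, 19037, 18810, 19006, 16774, 16967, 12201, 12272)
    ),
    OA42 = list(
      SAMtools = c(250786, 221062, 33158, 33168,
                   9454, 9022, 7492, 7566, 7116, 6967, 5916, 5994),
      FreeBayes = c(228122, 206493, 64847, 62467,
                    14581, 14200, 14205, 14385, 12942, 12789, 9873, 9936)
    )
  )
  out <- substitution_types()
  out$count <- counts[[line]][[caller]]
  out
}

#' Default EMS substitution spectrum
#'
#' Per-type probabilities proportional to the published OA70 FreeBayes
#' counts, in the order of [substitution_types()].
#'
#' @return Named numeric vector of 12 probabilities summing to 1.
#' @export
default_spectrum <- function() {
  counts <- ems_reference_counts("OA70", "FreeBayes")
  setNames(counts$count / sum(counts$count), counts$type)
}
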