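#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator.  Defaults emulate the
#' study system at toy scale: a hexaploid genome of 21 chromosomes split
#' into sub-genomes A, B and D whose total sizes keep the real ordering
#' B > A > D (5.180, 4.935 and 3.951 Gb scaled down by 1e4), an EMS mutation
#' density of one per 20,000 bases, and a 12-type substitution spectrum
#' proportional to the published OA70 FreeBayes counts.
#'
#' @param seed Integer seed governing every random draw of the module.
#' @param chromosome_spec Data frame with columns `name`, `subgenome`,
#'   `length` (bases).  Default: `default_chromosome_spec()`.
#' @param mutation_density Expected induced mutations per base (default
#'   `1/20000`).
#' @param spectrum Named vector of 12 probabilities over the substitution
#'   types of [substitution_types()], summing to 1.
#' @param n_background_variants Number of background polymorphisms shared
#'   between the control and every mutant sample.
#' @param n_genes Number of CDS gene models to plant in the genome.
#' @param noise_fraction Fraction of emitted records per sample that are
#'   low-confidence noise (depth <= 5 or quality <= 20).
#' @param n_mutant_samples Number of mutagenized samples to simulate.
#' @param subgenome_labels Declared sub-genome label set.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$mutation_density
#' @export
sim_config <- function(seed,
                       chromosome_spec = default_chromosome_spec(),
                       mutation_density = 1 / 20000,
                       spectrum = default_spectrum(),
                       n_background_variants = 200L,
                       n_genes = 30L,
                       noise_fraction = 0.05,
                       n_mutant_samples = 2L,
                       subgenome_labels = c("A", "B", "D")) {
  if (missing(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  seed <- as.integer(seed)
  chromosome_spec <- as.data.frame(chromosome_spec)
  need <- c("name", "subgenome", "length")
  if (!all(need %in% names(chromosome_spec))) {
    stop("chromosome_spec needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(chromosome_spec) == 0L) stop("chromosome_spec must be non-empty")
  if (any(chromosome_spec$length <= 0)) {
    stop("all chromosome lengths must be > 0")
  }
  if (anyDuplicated(chromosome_spec$name)) {
    stop("duplicated chromosome names in chromosome_spec")
  }
  bad_label <- !is.na(chromosome_spec$subgenome) &
    !(chromosome_spec$subgenome %in% subgenome_labels)
  if (any(bad_label)) {
    stop("sub-genome labels outside the declared set {",
         paste(subgenome_labels, collapse = ","), "}: ",
         paste(unique(chromosome_spec$subgenome[bad_label]), collapse = ", "))
  }
  if (mutation_density <= 0) stop("mutation_density must be > 0")
  types <- substitution_types()$type
  if (length(spectrum) != 12L) stop("spectrum must have 12 entries")
  if (is.null(names(spectrum))) names(spectrum) <- types
  if (!setequal(names(spectrum), types)) {
    stop("spectrum names must be the 12 substitution types")
  }
  spectrum <- spectrum[types]
  if (any(spectrum < 0) || abs(sum(spectrum) - 1) > 1e-9) {
    stop("spectrum entries must be non-negative and sum to 1 (tol 1e-9)")
  }
  if (noise_fraction < 0 || noise_fraction >= 1) {
    stop("noise_fraction must be in [0, 1)")
  }
  if (n_background_variants < 0 || n_genes < 0 || n_mutant_samples < 1) {
    stop("counts must be non-negative (and at least one mutant sample)")
  }
  structure(
    list(seed = seed,
         chromosome_spec = chromosome_spec,
         mutation_density = mutation_density,
         spectrum = spectrum,
         n_background_variants = as.integer(n_background_variants),
         n_genes = as.integer(n_genes),
         noise_fraction = noise_fraction,
         n_mutant_samples = as.integer(n_mutant_samples),
         subgenome_labels = subgenome_labels),
    class = "sim_config"
  )
}

#' Default toy chromosome layout
#'
#' 21 chromosomes named `chr1A` ... `chr7D`.  Per-sub-genome totals are the
#' published assembly sizes (B 5.180 Gb > A 4.935 Gb > D 3.951 Gb) scaled by
#' `scale`; within a sub-genome the seven chromosomes get mildly unequal
#' lengths so that length-proportional statistics are exercised.
#'
#' @param scale Bases of toy genome per Gb of real genome (default 1e5,
#'   i.e. a ~1.4 Mb toy genome).
#' @return Data frame with columns `name`, `subgenome`, `length`.
#' @export
default_chromosome_spec <- function(scale = 1e5) {
  totals <- c(A = 4.935, B = 5.180, D = 3.951) * scale
  # fixed weights, mildly unequal across the 7 chromosomes of a sub-genome
  w <- c(1.15, 1.1, 1.05, 1.0, 0.95, 0.9, 0.85)
  w <- w / sum(w)
  spec <- do.call(rbind, lapply(names(totals), function(sg) {
    data.frame(name = paste0("chr", 1:7, sg),
               subgenome = sg,
               length = round(totals[[sg]] * w),
               stringsAsFactors = FALSE)
  }))
  rownames(spec) <- NULL
  spec
}

#' @export
print.sim_config <- function(x, ...) {
  cat("EMS simulation config\n")
  cat("  seed:", x$seed, "\n")
  cat("  chromosomes:", nrow(x$chromosome_spec),
      sprintf("(total %s bases)", format(sum(x$chromosome_spec$length),
                                         big.mark = ",")), "\n")
  cat("  mutation density: 1 per", format(1 / x$mutation_density), "bases\n")
  cat("  mutant samples:", x$n_mutant_samples,
      " background variants:", x$n_background_variants,
      " genes:", x$n_genes, "\n")
  cat("  noise fraction:", x$noise_fraction, "\n")
  invisible(x)
}
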