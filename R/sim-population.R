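#' Simulate an EMS-mutagenized population as VCFs plus ground truth
#'
#' Emulates the variant-calling output of a resequencing experiment on
#' mutagenized lines and their unmutagenized parent:
#'
#' * per mutant sample, an induced-mutation count drawn Poisson with mean
#'   `mutation_density * genome_length`; each mutation's substitution type
#'   is drawn from the configured 12-type spectrum and placed uniformly
#'   among genome positions whose reference base matches the type's source
#'   base (collisions re-drawn);
#' * background polymorphisms (the parent line's divergence from the
#'   reference assembly) written into the control *and* every mutant
#'   sample, so control subtraction has something real to remove;
#' * low-confidence noise records with depth <= 5 or quality <= 20 — drawn
#'   so the strict filters `DP > 5 & QUAL > 20` exclude exactly the noise
#'   set; clean records always have depth >= 6 and quality > 20.
#'
#' All records are biallelic single-base substitutions, 1-based, sorted by
#' chromosome then position.  Every draw is governed by `config$seed`.
#'
#' @param genome A [ref_genome()] (use the edited genome returned by
#'   [make_gene_models()] when gene models are in play).
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, per-sample VCFs
#'   (`<sample>.vcf`), a control VCF (`control.vcf`) and ground-truth TSVs
#'   are written there.
#' @param mean_depth Mean sequencing depth for clean records (Poisson,
#'   truncated at 6; default 15, a typical resequencing coverage).
#' @return A list of class `ems_population`: `samples` (named list of
#'   [variant_set()]s), `control` (a [variant_set()]), `truth` (class
#'   `ems_ground_truth`: `induced`, `background`, `noise` data frames and
#'   `per_type_counts`), and `paths` when `out_dir` was given.
#' @examples
#' cfg <- sim_config(seed = 1, n_mutant_samples = 1)
#' g <- make_genome(cfg)
#' pop <- simulate_ems_population(g, cfg)
#' nrow(pop$truth$induced)
#' @export
simulate_ems_population <- function(genome, config, out_dir = NULL,
                                    mean_depth = 15) {
  stopifnot(inherits(genome, "ref_genome"), inherits(config, "sim_config"))
  set.seed(config$seed)
  types <- substitution_types()
  spectrum <- config$spectrum
  genome_len <- sum(genome$chrom$length)

  index <- base_position_index(genome)
  needed <- unique(types$ref[match(names(spectrum)[spectrum > 0],
                                   types$type)])
  absent <- needed[vapply(needed, function(b) index[[b]]$total == 0L,
                          logical(1))]
  if (length(absent) > 0L) {
    stop("spectrum requires source base(s) absent from the genome: ",
         paste(absent, collapse = ", "))
  }

  used <- new.env(parent = emptyenv())  # occupied "chrom:pos" keys

  # --- background polymorphisms, shared control + mutants ------------------
  background <- draw_background(genome, config$n_background_variants, used)

  # --- induced mutations per sample ----------------------------------------
  sample_ids <- sprintf("mut%02d", seq_len(config$n_mutant_samples))
  induced <- list()
  for (s in sample_ids) {
    n_s <- rpois(1L, config$mutation_density * genome_len)
    type_counts <- as.integer(stats::rmultinom(1L, n_s, spectrum))
    names(type_counts) <- names(spectrum)
    induced[[s]] <- draw_induced(index, type_counts, types, s, used)
  }
  induced_df <- do.call(rbind, c(induced, list(make.row.names = FALSE)))
  if (is.null(induced_df)) induced_df <- empty_variant_table(sample = TRUE)

  # --- noise records ---------------------------------------------------------
  f <- config$noise_fraction
  noise <- list()
  for (s in c(sample_ids, "control")) {
    n_real <- if (s == "control") nrow(background) else {
      sum(induced_df$sample == s) + nrow(background)
    }
    n_noise <- if (f > 0) round(f / (1 - f) * n_real) else 0L
    noise[[s]] <- draw_noise(genome, n_noise, s, used)
  }
  noise_df <- do.call(rbind, c(noise, list(make.row.names = FALSE)))

  # --- assemble per-sample record tables ------------------------------------
  clean_dp <- function(n) pmax(6L, rpois(n, mean_depth))
  clean_qual <- function(n) round(runif(n, 21, 60), 1)
  sets <- list()
  for (s in sample_ids) {
    ind <- induced_df[induced_df$sample == s,
                      c("chrom", "pos", "ref", "alt"), drop = FALSE]
    bg <- background[, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    clean <- rbind(ind, bg)
    clean$dp <- clean_dp(nrow(clean))
    clean$qual <- clean_qual(nrow(clean))
    nz <- noise_df[noise_df$sample == s,
                   c("chrom", "pos", "ref", "alt", "dp", "qual"),
                   drop = FALSE]
    sets[[s]] <- variant_set(s, sort_variants(rbind(clean, nz), genome))
  }
  ctl <- background[, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  ctl$dp <- clean_dp(nrow(ctl))
  ctl$qual <- clean_qual(nrow(ctl))
  ctl_noise <- noise_df[noise_df$sample == "control",
                        c("chrom", "pos", "ref", "alt", "dp", "qual"),
                        drop = FALSE]
  control <- variant_set("control", sort_variants(rbind(ctl, ctl_noise),
                                                  genome))

  per_type <- if (nrow(induced_df) > 0L) {
    stats::aggregate(list(count = rep(1L, nrow(induced_df))),
                     by = list(sample = induced_df$sample,
                               type = induced_df$type),
                     FUN = sum)
  } else {
    data.frame(sample = character(0), type = character(0),
               count = integer(0), stringsAsFactors = FALSE)
  }
  truth <- structure(
    list(induced = induced_df, background = background, noise = noise_df,
         per_type_counts = per_type, config = config),
    class = "ems_ground_truth"
  )
  out <- structure(list(samples = sets, control = control, truth = truth),
                   class = "ems_population")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    for (s in sample_ids) {
      paths[[s]] <- file.path(out_dir, paste0(s, ".vcf"))
      write_variants_vcf(sets[[s]], genome, paths[[s]])
    }
    paths$control <- file.path(out_dir, "control.vcf")
    write_variants_vcf(control, genome, paths$control)
    paths$truth_induced <- file.path(out_dir, "truth_induced.tsv")
    write.table(induced_df, paths$truth_induced, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths$truth_background <- file.path(out_dir, "truth_background.tsv")
    write.table(background, paths$truth_background, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths$truth_noise <- file.path(out_dir, "truth_noise.tsv")
    write.table(noise_df, paths$truth_noise, sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}

empty_variant_table <- function(sample = FALSE) {
  df <- data.frame(chrom = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   type = character(0), stringsAsFactors = FALSE)
  if (sample) df <- cbind(data.frame(sample = character(0)), df)
  df
}

# positions of each base, chromosome by chromosome, with cumulative offsets
# so a uniform draw over all genome positions carrying that base is a single
# sample.int() call
base_position_index <- function(genome) {
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (b in bases) {
    pos <- lapply(seq_along(genome$seq), function(i) {
      BiocGenerics::start(Biostrings::matchPattern(b, genome$seq[[i]]))
    })
    counts <- lengths(pos)
    out[[b]] <- list(pos = pos, counts = counts,
                     offsets = cumsum(c(0L, counts)), total = sum(counts))
  }
  out$chrom_names <- names(genome$seq)
  out
}

# draw n distinct (chrom, pos) uniformly among positions whose base is b,
# skipping keys already in `used`
draw_positions <- function(index, b, n, used, register = TRUE) {
  idx <- index[[b]]
  if (n == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (idx$total < n) stop("not enough ", b, " bases to place ", n, " variants")
  chrom_out <- character(0); pos_out <- integer(0)
  remaining <- n
  guard <- 0L
  while (remaining > 0L) {
    guard <- guard + 1L
    if (guard > 100L) stop("could not place variants without collision")
    draw <- sample.int(idx$total, min(idx$total, remaining * 2L))
    ci <- findInterval(draw - 1L, idx$offsets[-1]) + 1L
    pp <- integer(length(draw))
    for (i in unique(ci)) {
      sel <- ci == i
      pp[sel] <- idx$pos[[i]][draw[sel] - idx$offsets[i]]
    }
    keys <- paste0(index$chrom_names[ci], ":", pp)
    ok <- !duplicated(keys) & !vapply(keys, exists, logical(1), envir = used)
    keep <- which(ok)[seq_len(min(sum(ok), remaining))]
    if (length(keep) > 0L) {
      chrom_out <- c(chrom_out, index$chrom_names[ci[keep]])
      pos_out <- c(pos_out, pp[keep])
      if (register) {
        for (k in keys[keep]) assign(k, TRUE, envir = used)
      }
      remaining <- remaining - length(keep)
    }
  }
  data.frame(chrom = chrom_out, pos = pos_out, stringsAsFactors = FALSE)
}

draw_background <- function(genome, n, used) {
  if (n == 0L) {
    out <- empty_variant_table()
    return(out[, c("chrom", "pos", "ref", "alt")])
  }
  bases <- c("A", "C", "G", "T")
  chrom_out <- character(0); pos_out <- integer(0)
  remaining <- n
  guard <- 0L
  while (remaining > 0L) {
    guard <- guard + 1L
    if (guard > 100L) stop("could not place background variants")
    ci <- sample.int(nrow(genome$chrom), remaining * 2L, replace = TRUE,
                     prob = genome$chrom$length)
    pp <- floor(runif(length(ci)) * genome$chrom$length[ci]) + 1L
    keys <- paste0(genome$chrom$name[ci], ":", pp)
    ok <- !duplicated(keys) & !vapply(keys, exists, logical(1), envir = used)
    keep <- which(ok)[seq_len(min(sum(ok), remaining))]
    chrom_out <- c(chrom_out, genome$chrom$name[ci[keep]])
    pos_out <- c(pos_out, pp[keep])
    for (k in keys[keep]) assign(k, TRUE, envir = used)
    remaining <- remaining - length(keep)
  }
  ref <- genome_base(genome, chrom_out, pos_out)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  data.frame(chrom = chrom_out, pos = pos_out, ref = ref,
             alt = unname(alt), stringsAsFactors = FALSE)
}

draw_induced <- function(index, type_counts, types, sample_id, used) {
  # one shared position register across samples: at toy densities the
  # chance of two samples hitting the same base is negligible, and keeping
  # all emitted keys distinct makes the ground-truth accounting exact
  rows <- list()
  for (b in c("A", "C", "G", "T")) {
    tt <- types$type[types$ref == b]
    m_b <- sum(type_counts[tt])
    if (m_b == 0L) next
    posdf <- draw_positions(index, b, m_b, used, register = TRUE)
    alt <- rep(types$alt[match(tt, types$type)], times = type_counts[tt])
    alt <- sample(alt)  # shuffle type assignment over positions
    rows[[b]] <- data.frame(sample = sample_id, chrom = posdf$chrom,
                            pos = posdf$pos, ref = b, alt = alt,
                            type = paste0(b, ">", alt),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- empty_variant_table(sample = TRUE)
  out
}

draw_noise <- function(genome, n, sample_id, used) {
  if (n == 0L) {
    out <- data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), dp = integer(0),
                      qual = numeric(0), stringsAsFactors = FALSE)
    return(out)
  }
  base <- draw_background(genome, n, used)  # same uniform placement
  mode <- sample(1:3, n, replace = TRUE)    # 1 low DP, 2 low QUAL, 3 both
  dp <- ifelse(mode %in% c(1L, 3L), sample(0:5, n, replace = TRUE),
               pmax(6L, rpois(n, 15)))
  qual <- ifelse(mode %in% c(2L, 3L), round(runif(n, 0, 20), 1),
                 round(runif(n, 21, 60), 1))
  data.frame(sample = sample_id, chrom = base$chrom, pos = base$pos,
             ref = base$ref, alt = base$alt, dp = as.integer(dp),
             qual = qual, stringsAsFactors = FALSE)
}

sort_variants <- function(df, genome) {
  ord <- order(match(df$chrom, genome$chrom$name), df$pos)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
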