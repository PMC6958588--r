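#' Default phenotype effect model
#'
#' Group-level parameters for the phenotype simulator, chosen to emulate
#' the study's structure:
#'
#' * germination: a salt-tolerant line germinates with probability 0.8 at
#'   200 mM NaCl, a non-tolerant mutant line with 0.2 (the parent line's
#'   germination collapsed to ~20-30% at that concentration); at 0 mM both
#'   germinate at 0.95.
#' * root/shoot pouch assay: group means and SDs at 50/100/150 mM NaCl
#'   taken from the published comparison of the 70 selected lines against
#'   the parent (e.g. root at 50 mM: 28.13 +/- 11.39 cm vs
#'   21.36 +/- 10.14 cm).
#' * field trial: mutant-like lines and two control-like entries whose
#'   group means differ by several SDs on germination, height, spike
#'   length, kernels per spike, tillering and per-seed production, so the
#'   controls sit far from the mutant cloud exactly as the parent controls
#'   did in the field.
#'
#' @return A list with components `germination`, `pouch`, `field`.
#' @export
default_effect_model <- function() {
  list(
    germination = data.frame(
      group = rep(c("tolerant", "non_tolerant"), each = 2),
      salt = "NaCl",
      concentration = c(0, 200, 0, 200),
      prob = c(0.95, 0.8, 0.95, 0.2),
      stringsAsFactors = FALSE
    ),
    pouch = data.frame(
      group = rep(c("mutant", "control"), each = 3),
      concentration = rep(c(50, 100, 150), 2),
      root_mean = c(28.13, 16.57, 8.77, 21.36, 11.77, 6.39),
      root_sd = c(11.39, 9.59, 6.616, 10.14, 8.78, 6.173),
      shoot_mean = c(4.294, 2.278, 1.138, 3.606, 1.778, 0.773),
      shoot_sd = c(2.232, 1.743, 1.208, 1.645, 1.686, 0.790),
      stringsAsFactors = FALSE
    ),
    field = data.frame(
      group = c("mutant", "control_sweden", "control_bangladesh"),
      germination_prob = c(0.72, 0.15, 0.47),
      height_mean = c(65, 50, 55), height_sd = c(3, 3, 3),
      tiller_ratio_mean = c(1.3, 0.8, 0.8), tiller_ratio_sd = c(0.15, 0.15, 0.15),
      spike_mean = c(3.2, 2.4, 2.4), spike_sd = c(0.25, 0.25, 0.25),
      kernels_mean = c(38, 27, 27), kernels_sd = c(3, 3, 3),
      fungal_mean = c(15, 35, 35), fungal_sd = c(5, 5, 5),
      insect_mean = c(8, 22, 22), insect_sd = c(4, 4, 4),
      production_mean = c(1.6, 1.0, 1.1), production_sd = c(0.15, 0.15, 0.15),
      stringsAsFactors = FALSE
    )
  )
}

# zero-truncated normal: redraw negatives rather than clamping, so the
# distribution has no point mass at 0; sd = 0 degenerates to the mean
rtruncnorm0 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  guard <- 0L
  while (any(x < 0)) {
    guard <- guard + 1L
    if (guard > 1000L) stop("truncated-normal rejection did not converge")
    x[x < 0] <- rnorm(sum(x < 0), mean, sd)
  }
  x
}

#' Simulate phenotype tables
#'
#' Generates the three phenotype tables the analysis consumes, with the
#' group mean/SD structure of [default_effect_model()]:
#'
#' * `germination` — one record per line, salt level and concentration;
#'   germinated counts are binomial draws.
#' * `pouch` — root/shoot lengths per seedling; zero-truncated normal
#'   draws per group and NaCl concentration.
#' * `field` — one row per line with all field-trial variables (total
#'   seed sown, germinated, height, tillers, spike length, kernels per
#'   spike, fungal and insect percentages, grain weight).
#'
#' @param n_lines Number of mutant lines in the germination screen.
#' @param effect_model See [default_effect_model()].
#' @param seed Integer seed.
#' @param n_tolerant Number of lines that are truly salt tolerant.
#' @param seeds_per_line Seeds sown per line in the germination screen.
#' @param pouch_n Seedlings per group per concentration in the pouch assay.
#' @param field_lines Mutant-like lines in the field table.
#' @param field_seeds Seeds sown per line in the field.
#' @return List of class `phenotype_tables`: `germination`, `pouch`,
#'   `field`, `truth` (which line ids are truly tolerant).
#' @examples
#' pt <- simulate_phenotypes(n_lines = 100, seed = 1, n_tolerant = 5)
#' head(pt$germination)
#' @export
simulate_phenotypes <- function(n_lines,
                                effect_model = default_effect_model(),
                                seed,
                                n_tolerant = max(1L, round(0.042 * n_lines)),
                                seeds_per_line = 10L,
                                pouch_n = 100L,
                                field_lines = 70L,
                                field_seeds = 99L) {
  stopifnot(n_lines >= 1, n_tolerant <= n_lines)
  gm <- effect_model$germination
  if (any(gm$prob < 0 | gm$prob > 1)) {
    stop("germination probabilities must be in [0, 1]")
  }
  if (any(effect_model$field$germination_prob < 0 |
          effect_model$field$germination_prob > 1)) {
    stop("field germination probabilities must be in [0, 1]")
  }
  set.seed(seed)

  line_ids <- sprintf("L%04d", seq_len(n_lines))
  tolerant <- sample(line_ids, n_tolerant)
  group_of <- ifelse(line_ids %in% tolerant, "tolerant", "non_tolerant")

  germ <- do.call(rbind, lapply(seq_len(nrow(gm)), function(i) {
    sel <- group_of == gm$group[i]
    if (!any(sel)) return(NULL)
    data.frame(line_id = line_ids[sel],
               salt = gm$salt[i],
               concentration = gm$concentration[i],
               seeds_sown = seeds_per_line,
               seeds_germinated = rbinom(sum(sel), seeds_per_line,
                                         gm$prob[i]),
               stringsAsFactors = FALSE)
  }))
  germ <- germ[order(germ$line_id, germ$salt, germ$concentration), ]
  rownames(germ) <- NULL

  pm <- effect_model$pouch
  pouch <- do.call(rbind, lapply(seq_len(nrow(pm)), function(i) {
    data.frame(line_id = sprintf("%s_c%d_%03d", pm$group[i],
                                 pm$concentration[i], seq_len(pouch_n)),
               group = pm$group[i],
               concentration = pm$concentration[i],
               root_length = rtruncnorm0(pouch_n, pm$root_mean[i],
                                         pm$root_sd[i]),
               shoot_length = rtruncnorm0(pouch_n, pm$shoot_mean[i],
                                          pm$shoot_sd[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(pouch) <- NULL

  fm <- effect_model$field
  groups <- c(rep("mutant", field_lines), "control_sweden",
              "control_bangladesh")
  fi <- match(groups, fm$group)
  n_f <- length(groups)
  germinated <- rbinom(n_f, field_seeds, fm$germination_prob[fi])
  germinated <- pmax(germinated, 1L)  # a fully failed plot has no ratios
  tillers <- round(pmax(0, rnorm(n_f, fm$tiller_ratio_mean[fi],
                                 fm$tiller_ratio_sd[fi])) * germinated)
  production <- rtruncnorm0(n_f, fm$production_mean[fi],
                            fm$production_sd[fi])
  field <- data.frame(
    line_id = c(sprintf("OA%03d", seq_len(field_lines)), "BARI_SE",
                "BARI_BD"),
    group = groups,
    total_seed_sown = field_seeds,
    total_germinated = germinated,
    average_height_cm = rtruncnorm0(n_f, fm$height_mean[fi],
                                    fm$height_sd[fi]),
    harvested_tillers = as.integer(tillers),
    spike_length_cm = rtruncnorm0(n_f, fm$spike_mean[fi], fm$spike_sd[fi]),
    kernels_per_spike = round(rtruncnorm0(n_f, fm$kernels_mean[fi],
                                          fm$kernels_sd[fi])),
    fungal_pct = pmin(100, rtruncnorm0(n_f, fm$fungal_mean[fi],
                                       fm$fungal_sd[fi])),
    insect_pct = pmin(100, rtruncnorm0(n_f, fm$insect_mean[fi],
                                       fm$insect_sd[fi])),
    total_grain_weight_g = production * germinated,
    stringsAsFactors = FALSE
  )

  structure(list(germination = germ, pouch = pouch, field = field,
                 truth = list(tolerant_lines = sort(tolerant))),
            class = "phenotype_tables")
}

#' Write phenotype tables as TSV
#'
#' @param pt A `phenotype_tables` object.
#' @param dir Output directory (created if needed); writes
#'   `germination.tsv`, `pouch.tsv`, `field.tsv`.
#' @return `dir`, invisibly.
#' @export
write_phenotypes <- function(pt, dir) {
  stopifnot(inherits(pt, "phenotype_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("germination", "pouch", "field")) {
    write.table(pt[[nm]], file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read phenotype tables written by [write_phenotypes()]
#'
#' @param dir Directory containing the three TSV files.
#' @return A `phenotype_tables` object (without the simulation truth).
#' @export
read_phenotypes <- function(dir) {
  out <- lapply(c(germination = "germination", pouch = "pouch",
                  field = "field"), function(nm) {
    read.delim(file.path(dir, paste0(nm, ".tsv")), sep = "\t",
               stringsAsFactors = FALSE)
  })
  structure(c(out, list(truth = NULL)), class = "phenotype_tables")
}
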