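test_that("derived field metrics follow their definitions", {
  df <- data.frame(line_id = c("a", "b", "c"),
                   total_seed_sown = c(99L, 99L, 99L),
                   total_germinated = c(15L, 33L, 14L),
                   harvested_tillers = c(12L, 33L, 20L),
                   total_grain_weight_g = c(28, 40, 28))
  out <- derive_metrics(df)
  expect_equal(round(out$germination_pct[1], 2), 15.15)
  expect_equal(out$tillering_pct[2], 100)
  expect_equal(out$production_per_germinated[3], 2.0)
  # zero germinated: ratios absent and flagged
  z <- df; z$total_germinated[1] <- 0L
  oz <- derive_metrics(z)
  expect_true(is.na(oz$tillering_pct[1]))
  expect_false(oz$ratio_defined[1])
  expect_error(derive_metrics(df[, -2]), "lacks column")
})

boundary_line <- function(...) {
  base <- data.frame(line_id = "x", total_seed_sown = 100L,
                     total_germinated = 60L, harvested_tillers = 60L,
                     spike_length_cm = 2.55, kernels_per_spike = 30L,
                     fungal_pct = 29.9, insect_pct = 19.9,
                     total_grain_weight_g = 60,
                     stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("cut-off boundaries follow the quoted inclusive/strict semantics", {
  # every criterion exactly at its passing boundary
  expect_equal(as.character(apply_cutoffs(boundary_line())), "x")
  # "over 2.54 cm" is strict
  expect_length(apply_cutoffs(boundary_line(spike_length_cm = 2.54)), 0L)
  # "less than 30%" fungal is strict
  expect_length(apply_cutoffs(boundary_line(fungal_pct = 30)), 0L)
  # "below 20%" insect is strict
  expect_length(apply_cutoffs(boundary_line(insect_pct = 20)), 0L)
  # "at least 60%" germination is inclusive; 59.x fails
  expect_length(apply_cutoffs(boundary_line(total_germinated = 59L,
                                            harvested_tillers = 59L,
                                            total_grain_weight_g = 59)), 0L)
  # "minimum of 30 kernels" inclusive; 29 fails
  expect_length(apply_cutoffs(boundary_line(kernels_per_spike = 29L)), 0L)
  rep <- attr(apply_cutoffs(boundary_line(fungal_pct = 30)), "report")
  expect_match(rep$reason, "fungal")
})

test_that("lines with missing fields are excluded with a recorded reason", {
  df <- rbind(boundary_line(), boundary_line())
  df$line_id <- c("ok", "bad")
  df$kernels_per_spike[2] <- NA
  sel <- apply_cutoffs(df)
  expect_equal(as.character(sel), "ok")
  rep <- attr(sel, "report")
  expect_match(rep$reason[rep$line_id == "bad"], "missing: kernels")
})

test_that("apply_cutoffs equals a brute-force row filter on a simulated table", {
  pt <- simulate_phenotypes(n_lines = 10, seed = 23, field_lines = 120)
  field <- derive_metrics(pt$field)
  sel <- as.character(apply_cutoffs(field))
  brute <- field$line_id[
    field$germination_pct >= 60 &
      field$harvested_tillers / field$total_germinated >= 1 &
      field$spike_length_cm > 2.54 &
      field$kernels_per_spike >= 30 &
      field$fungal_pct < 30 &
      field$insect_pct < 20 &
      field$production_per_germinated >= 1]
  expect_equal(sel, brute)
  # the control-like entries never clear the strict cut-offs
  expect_false(any(c("BARI_SE", "BARI_BD") %in% sel))
})

test_that("PCA satisfies the eigendecomposition identities", {
  set.seed(5)
  x <- matrix(rnorm(200 * 6), ncol = 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  x <- sweep(x, 2, c(1, 2, 4, 8, 16, 32), "*")
  p <- run_pca(x)
  k <- ncol(x)
  # orthonormal loadings
  expect_equal(crossprod(p$loadings), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)
  # eigenvalues descending, non-negative
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_true(all(p$eigenvalues >= 0))
  # score-column variance equals the eigenvalue
  expect_equal(unname(apply(p$scores, 2, var)), p$eigenvalues,
               tolerance = 1e-8)
  # exact reconstruction of the processed matrix
  xp <- sweep(sweep(x, 2, p$center), 2, p$scale, "/")
  expect_equal(p$scores %*% t(p$loadings), xp, tolerance = 1e-8,
               ignore_attr = TRUE)
  # total variance identity
  expect_equal(sum(p$eigenvalues), sum(apply(xp, 2, var)),
               tolerance = 1e-8)
  # sign convention: largest-magnitude loading entry positive
  for (j in seq_len(k)) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
})

test_that("2x2 eigenvalues match the closed-form quadratic roots", {
  set.seed(11)
  x <- matrix(rnorm(400), ncol = 2) %*% matrix(c(2, 0.8, 0, 0.5), 2)
  p <- run_pca(x, standardize = FALSE)
  cv <- cov(sweep(x, 2, colMeans(x)))
  tr <- cv[1, 1] + cv[2, 2]
  det_ <- cv[1, 1] * cv[2, 2] - cv[1, 2]^2
  roots <- c((tr + sqrt(tr^2 - 4 * det_)) / 2,
             (tr - sqrt(tr^2 - 4 * det_)) / 2)
  expect_equal(p$eigenvalues, roots, tolerance = 1e-8)
})

test_that("a duplicated column collapses onto one component", {
  set.seed(2)
  a <- rnorm(50)
  p <- run_pca(cbind(a = a, b = a))
  expect_equal(p$eigenvalues[2], 0, tolerance = 1e-8)
  expect_equal(p$explained[1], 1, tolerance = 1e-8)
})

test_that("constant columns are refused by name; incomplete rows are dropped and reported", {
  x <- cbind(a = rnorm(10), flat = rep(3, 10))
  expect_error(run_pca(x), "flat")
  y <- cbind(a = rnorm(10), b = rnorm(10))
  y[c(2, 7), 2] <- NA
  p <- run_pca(y)
  expect_equal(p$dropped_rows, c(2L, 7L))
  expect_equal(nrow(p$scores), 8L)
})

test_that("control-like lines are the top score-distance outliers", {
  pt <- simulate_phenotypes(n_lines = 10, seed = 29, field_lines = 70)
  field <- derive_metrics(pt$field)
  vars <- c("total_seed_sown", "total_germinated", "germination_pct",
            "average_height_cm", "harvested_tillers", "tillering_pct",
            "spike_length_cm", "kernels_per_spike", "fungal_pct",
            "total_grain_weight_g", "production_per_germinated")
  # total_seed_sown is constant by design; drop it as any analyst would
  m <- field[, setdiff(vars, "total_seed_sown")]
  rownames(m) <- field$line_id
  p <- run_pca(m)
  d <- score_distances(p)
  expect_setequal(d$row[1:2], c("BARI_SE", "BARI_BD"))
})
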