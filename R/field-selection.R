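#' Derive the field-trial metrics
#'
#' Adds the derived per-line variables to a field table:
#' `germination_pct = 100 * germinated / sown`,
#' `tillering_pct = 100 * harvested_tillers / germinated` and
#' `production_per_germinated = grain_weight / germinated` (grams per
#' germinated seed).  Lines with zero germinated seeds get `NA` ratio
#' metrics and are flagged in `ratio_defined`.
#'
#' @param records Field data frame with columns `total_seed_sown`,
#'   `total_germinated`, `harvested_tillers`, `total_grain_weight_g`.
#' @return `records` with the derived columns appended.
#' @examples
#' df <- data.frame(total_seed_sown = 99, total_germinated = 15,
#'                  harvested_tillers = 12, total_grain_weight_g = 28)
#' round(derive_metrics(df)$germination_pct, 2)  # 15.15
#' @export
derive_metrics <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("total_seed_sown", "total_germinated", "harvested_tillers",
            "total_grain_weight_g")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0L) {
    stop("field table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(records$total_germinated > records$total_seed_sown)) {
    stop("total_germinated exceeds total_seed_sown for some line(s)")
  }
  out <- records
  out$germination_pct <- 100 * out$total_germinated / out$total_seed_sown
  ok <- out$total_germinated > 0
  out$tillering_pct <- ifelse(ok, 100 * out$harvested_tillers /
                                out$total_germinated, NA_real_)
  out$production_per_germinated <- ifelse(ok, out$total_grain_weight_g /
                                            out$total_germinated, NA_real_)
  out$ratio_defined <- ok
  out
}

#' Default field-trial cut-offs
#'
#' The seven selection criteria with their exact boundary semantics:
#' germination rate *at least* 60% (inclusive), harvested tillers per
#' germinated seed *at least* 1 (inclusive), spike length *over* 2.54 cm
#' (strict), a *minimum* of 30 kernels per spike (inclusive), *less than*
#' 30% fungal infection (strict), *below* 20% insect infestation (strict),
#' and *minimum* 1 g per germinated seed of production (inclusive).
#'
#' @return Named list of cut-off values.
#' @export
default_cutoffs <- function() {
  list(min_germination_pct = 60,     # inclusive
       min_tillers_per_germinated = 1,  # inclusive
       min_spike_length_cm = 2.54,   # exclusive ("over")
       min_kernels_per_spike = 30,   # inclusive
       max_fungal_pct = 30,          # exclusive ("less than")
       max_insect_pct = 20,          # exclusive ("below")
       min_production_per_germinated = 1)  # inclusive
}

#' Apply the multi-criterion field cut-off filter
#'
#' A line is selected iff it passes all seven criteria of
#' [default_cutoffs()] with their quoted boundary semantics.  Lines with a
#' missing value in any required field are excluded with the reason
#' recorded, never silently dropped.
#'
#' @param records Field data frame; derived metrics are computed via
#'   [derive_metrics()] if absent.
#' @param cutoffs Named list as returned by [default_cutoffs()].
#' @return Character vector of selected `line_id`s, with attribute
#'   `report`: a data frame with one logical column per criterion, a
#'   `selected` column and a `reason` string for every line.
#' @examples
#' df <- data.frame(line_id = "x", total_seed_sown = 100,
#'                  total_germinated = 60, harvested_tillers = 60,
#'                  spike_length_cm = 2.55, kernels_per_spike = 30,
#'                  fungal_pct = 29.9, insect_pct = 19.9,
#'                  total_grain_weight_g = 60)
#' apply_cutoffs(df)  # boundary line: selected
#' @export
apply_cutoffs <- function(records, cutoffs = default_cutoffs()) {
  stopifnot(is.data.frame(records))
  if (!("germination_pct" %in% names(records))) {
    records <- derive_metrics(records)
  }
  if (!("line_id" %in% names(records))) {
    records$line_id <- sprintf("line%03d", seq_len(nrow(records)))
  }
  tillers_ratio <- records$harvested_tillers / records$total_germinated
  checks <- data.frame(
    germination = records$germination_pct >= cutoffs$min_germination_pct,
    tillers = tillers_ratio >= cutoffs$min_tillers_per_germinated,
    spike = records$spike_length_cm > cutoffs$min_spike_length_cm,
    kernels = records$kernels_per_spike >= cutoffs$min_kernels_per_spike,
    fungal = records$fungal_pct < cutoffs$max_fungal_pct,
    insect = records$insect_pct < cutoffs$max_insect_pct,
    production = records$production_per_germinated >=
      cutoffs$min_production_per_germinated
  )
  has_missing <- apply(is.na(checks), 1L, any)
  pass <- !has_missing & apply(checks, 1L, all)
  reason <- vapply(seq_len(nrow(checks)), function(i) {
    if (has_missing[i]) {
      paste("missing:", paste(names(checks)[is.na(checks[i, ])],
                              collapse = ","))
    } else if (pass[i]) {
      "selected"
    } else {
      paste("failed:", paste(names(checks)[!unlist(checks[i, ])],
                             collapse = ","))
    }
  }, character(1))
  report <- cbind(data.frame(line_id = records$line_id,
                             stringsAsFactors = FALSE),
                  checks, selected = pass, reason = reason)
  structure(records$line_id[pass], report = report)
}

#' Principal component analysis as a covariance eigendecomposition
#'
#' Centers (and by default unit-scales) the columns of the data matrix,
#' eigendecomposes its covariance matrix, and projects the processed
#' matrix onto the eigenvectors.  Components are ordered by descending
#' eigenvalue; each loading column's sign is fixed so its
#' largest-magnitude element is positive, making reports reproducible.
#' Rows with missing cells are dropped and reported.
#'
#' @param x Numeric matrix or data frame, N observations x K variables
#'   (non-numeric columns such as line ids are dropped with a message-free
#'   record in the result).
#' @param standardize Scale columns to unit variance (default `TRUE`:
#'   the field variables mix counts, centimetres, grams and percentages).
#'   A constant column cannot be standardized and raises an error naming
#'   it.
#' @return Object of class `pca_result`: `loadings` (K x K, orthonormal
#'   columns), `eigenvalues` (descending), `scores` (N x K),
#'   `explained` (variance shares), `center`, `scale`, `dropped_rows`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), ncol = 2)
#' p <- run_pca(x)
#' sum(p$explained)  # 1
#' @export
run_pca <- function(x, standardize = TRUE) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    rn <- if ("line_id" %in% names(x)) x$line_id else rownames(x)
    x <- as.matrix(x[, num, drop = FALSE])
    if (!is.null(rn)) rownames(x) <- rn
  }
  if (!is.numeric(x)) stop("x must be numeric")
  complete <- stats::complete.cases(x)
  dropped <- which(!complete)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 2L) stop("need at least 2 complete observations")
  if (k < 1L) stop("need at least 1 variable")
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  if (standardize) {
    s <- apply(x, 2L, sd)
    constant <- s == 0 | is.na(s)
    if (any(constant)) {
      stop("constant column(s) cannot be standardized: ",
           paste(colnames(x)[constant], collapse = ", "))
    }
    xc <- sweep(xc, 2L, s, "/")
  } else {
    s <- rep(1, k)
  }
  cv <- stats::cov(xc)
  eig <- eigen(cv, symmetric = TRUE)
  values <- eig$values
  values[values < 0 & values > -1e-8] <- 0  # numerical jitter only
  if (any(values < 0)) stop("covariance eigendecomposition failed")
  vectors <- eig$vectors
  # deterministic sign: largest-magnitude element of each column positive
  for (j in seq_len(k)) {
    m <- which.max(abs(vectors[, j]))
    if (vectors[m, j] < 0) vectors[, j] <- -vectors[, j]
  }
  scores <- xc %*% vectors
  colnames(vectors) <- colnames(scores) <- paste0("PC", seq_len(k))
  rownames(vectors) <- colnames(x)
  structure(list(loadings = vectors,
                 eigenvalues = values,
                 scores = scores,
                 explained = if (sum(values) > 0) values / sum(values)
                             else rep(NA_real_, k),
                 center = center, scale = s,
                 standardized = standardize,
                 dropped_rows = dropped),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat("PCA (covariance eigendecomposition):", nrow(x$scores),
      "observations,", k, "variables\n")
  show <- seq_len(min(4L, k))
  cat("  explained variance:",
      paste(sprintf("%s %.1f%%", paste0("PC", show),
                    100 * x$explained[show]), collapse = ", "), "\n")
  if (length(x$dropped_rows) > 0L) {
    cat("  dropped", length(x$dropped_rows), "incomplete row(s)\n")
  }
  invisible(x)
}

#' Score-distance outlier ranking
#'
#' Euclidean distance of each observation's component scores from the
#' score centroid (the origin, since columns are centered), over the first
#' `k` components.  Lines far from the cloud — the way the unmutagenized
#' controls separated from the mutant lines in the field PCA — rank first.
#'
#' @param pca A [run_pca()] result.
#' @param k Number of leading components (default: all).
#' @return Data frame `row`, `distance`, sorted descending.
#' @export
score_distances <- function(pca, k = NULL) {
  stopifnot(inherits(pca, "pca_result"))
  if (is.null(k)) k <- ncol(pca$scores)
  d <- sqrt(rowSums(pca$scores[, seq_len(k), drop = FALSE]^2))
  nm <- rownames(pca$scores)
  if (is.null(nm)) nm <- as.character(seq_along(d))
  out <- data.frame(row = nm, distance = d, stringsAsFactors = FALSE)
  out <- out[order(-out$distance), ]
  rownames(out) <- NULL
  out
}
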