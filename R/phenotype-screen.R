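#' Germination rate in percent
#'
#' @param seeds_germinated,seeds_sown Integer counts (vectors recycled);
#'   alternatively pass a data frame with those two columns as the first
#'   argument.
#' @return Numeric percentage(s), `100 * germinated / sown`.
#' @examples
#' germination_rate(7, 10)   # 70
#' @export
germination_rate <- function(seeds_germinated, seeds_sown) {
  if (is.data.frame(seeds_germinated)) {
    df <- seeds_germinated
    seeds_sown <- df$seeds_sown
    seeds_germinated <- df$seeds_germinated
  }
  if (any(seeds_sown <= 0)) stop("seeds_sown must be > 0")
  if (any(seeds_germinated < 0 | seeds_germinated > seeds_sown)) {
    stop("seeds_germinated must be between 0 and seeds_sown")
  }
  100 * seeds_germinated / seeds_sown
}

#' Select salt-tolerant lines from a germination screen
#'
#' A line counts as strongly salt tolerant when its germination rate at the
#' screening concentration is at or above the threshold (the comparison is
#' inclusive: 70% germination passes a 70% threshold).  Lines without a
#' record at the required salt/concentration cannot be scored; they are
#' excluded and reported in the `missing` attribute, never silently
#' dropped.
#'
#' @param records Data frame of germination records (`line_id`, `salt`,
#'   `concentration`, `seeds_sown`, `seeds_germinated`).
#' @param threshold Germination-rate threshold in percent (default 70).
#' @param at_concentration Screening concentration in mM (default 200).
#' @param salt Salt used for the screen (default `"NaCl"`).
#' @return Character vector of selected `line_id`s (sorted), with
#'   attributes `rates` (named rates of all scored lines) and `missing`
#'   (line ids lacking the required record).
#' @examples
#' recs <- data.frame(line_id = c("L1", "L2"), salt = "NaCl",
#'                    concentration = 200, seeds_sown = 10,
#'                    seeds_germinated = c(7, 6))
#' select_tolerant(recs)   # L1 only: 70% passes, 60% does not
#' @export
select_tolerant <- function(records, threshold = 70,
                            at_concentration = 200, salt = "NaCl") {
  stopifnot(is.data.frame(records))
  all_lines <- unique(records$line_id)
  at <- records[records$salt == salt &
                  records$concentration == at_concentration, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("no records at ", at_concentration, " mM ", salt)
  }
  # several records per line (e.g. replicate dishes) are pooled
  germ <- tapply(at$seeds_germinated, at$line_id, sum)
  sown <- tapply(at$seeds_sown, at$line_id, sum)
  rates <- 100 * germ / sown
  selected <- sort(names(rates)[rates >= threshold])
  missing <- sort(setdiff(all_lines, names(rates)))
  structure(selected, rates = rates, missing = missing)
}

#' Group statistics and t-test for the root/shoot pouch assay
#'
#' Compares a response (root or shoot length) between the two groups at one
#' NaCl concentration: per-group mean, sample SD and n, plus a two-sided
#' two-sample t-test.  Welch's unequal-variance test is the default (the
#' groups' SDs differ); a pooled-variance test is available via
#' `var_equal = TRUE`.
#'
#' @param records Pouch data frame (`group`, `concentration`, and the
#'   response column).
#' @param concentration NaCl concentration (mM) to analyse.
#' @param response `"root_length"` or `"shoot_length"`.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param alpha Significance level for the `significant` flag.
#' @return List: `stats` (data frame `group`, `n`, `mean`, `sd`),
#'   `t_statistic`, `df`, `p_value`, `significant`, `method`.
#' @examples
#' pt <- simulate_phenotypes(n_lines = 10, seed = 1)
#' group_stats(pt$pouch, concentration = 50)$p_value
#' @export
group_stats <- function(records, concentration,
                        response = c("root_length", "shoot_length"),
                        var_equal = FALSE, alpha = 0.05) {
  response <- match.arg(response)
  x <- records[records$concentration == concentration, , drop = FALSE]
  if (nrow(x) == 0L) stop("no records at ", concentration, " mM")
  groups <- sort(unique(x$group))
  if (length(groups) != 2L) {
    stop("need exactly 2 groups at ", concentration, " mM; found ",
         length(groups))
  }
  values <- split(x[[response]], x$group)
  n <- vapply(values, length, integer(1))
  if (any(n < 2L)) {
    stop("each group needs >= 2 observations (got ",
         paste(n, collapse = ", "), ")")
  }
  stats_df <- data.frame(group = groups,
                         n = as.integer(n[groups]),
                         mean = vapply(values[groups], mean, numeric(1)),
                         sd = vapply(values[groups], sd, numeric(1)),
                         stringsAsFactors = FALSE)
  rownames(stats_df) <- NULL
  if (all(stats_df$sd == 0) &&
      stats_df$mean[1] == stats_df$mean[2]) {
    # identical constant groups: t.test() refuses (zero variance); by
    # convention there is no evidence of a difference
    return(list(stats = stats_df, t_statistic = 0,
                df = sum(stats_df$n) - 2, p_value = 1,
                significant = FALSE,
                method = if (var_equal) "pooled t-test" else "Welch t-test"))
  }
  tt <- t.test(values[[groups[1]]], values[[groups[2]]],
               var.equal = var_equal)
  list(stats = stats_df,
       t_statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = tt$p.value,
       significant = tt$p.value < alpha,
       method = tt$method)
}
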