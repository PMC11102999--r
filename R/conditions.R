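#' Design levels of the simulation study
#'
#' The factor-retention comparison crosses sample size, number of factors,
#' indicators per factor, primary- and cross-loading levels, inter-factor
#' correlation, number of response categories and the distribution of the
#' underlying continuous variables.
#'
#' @format A named list of level vectors.
#' @export
design_levels <- list(
  n          = c(300L, 600L, 1000L),
  k          = c(5L, 10L),
  m          = c(1L, 2L, 4L),
  rho        = c(0, 0.3, 0.6),
  primary    = c("low", "medium", "high"),
  cross      = c("low", "medium", "high"),
  dist       = c("normal", "normal-skewed", "non-normal", "non-normal-skewed"),
  categories = c(4L, 5L)
)

# Uniform ranges behind the loading labels
.primary_ranges <- list(low = c(0.35, 0.50), medium = c(0.50, 0.65),
                        high = c(0.65, 0.80))
.cross_ranges   <- list(low = c(0.00, 0.10), medium = c(0.10, 0.20),
                        high = c(0.20, 0.30))

#' Uniform range for a loading-level label
#'
#' Primary loadings are drawn from `[0.35, 0.50]` (low), `[0.50, 0.65]`
#' (medium) or `[0.65, 0.80]` (high); cross-loadings from `[0, 0.10]`,
#' `[0.10, 0.20]` or `[0.20, 0.30]`.
#'
#' @param level `"low"`, `"medium"` or `"high"`.
#' @param type `"primary"` or `"cross"`.
#' @return Numeric vector `c(lower, upper)`.
#' @export
loading_range <- function(level, type = c("primary", "cross")) {
  type <- match.arg(type)
  tab <- if (type == "primary") .primary_ranges else .cross_ranges
  if (!level %in% names(tab)) {
    stop("unknown loading level: ", level, call. = FALSE)
  }
  tab[[level]]
}

#' Specify one simulation condition
#'
#' A condition fixes every design factor of a simulation cell: sample size,
#' number of latent factors, indicators per factor, loading levels,
#' inter-factor correlation, number of ordinal categories and the type of
#' underlying continuous distribution. Single-factor conditions must have
#' `rho = 0`; their cross-loading level is inert (there is no second factor
#' to cross-load on) but is kept for bookkeeping.
#'
#' @param n Sample size (300, 600 or 1000).
#' @param m Number of latent factors (1, 2 or 4).
#' @param k Indicators per factor (5 or 10).
#' @param primary Primary-loading level: `"low"`, `"medium"` or `"high"`.
#' @param cross Cross-loading level; ignored when `m = 1`.
#' @param rho Inter-factor correlation (0, 0.3 or 0.6; must be 0 when
#'   `m = 1`).
#' @param categories Number of ordinal categories (4 or 5).
#' @param dist Underlying continuous distribution: `"normal"`,
#'   `"normal-skewed"`, `"non-normal"` or `"non-normal-skewed"`. The
#'   `-skewed` suffix selects asymmetric discretization thresholds;
#'   `non-` selects non-normal continuous data (skewness 2, excess
#'   kurtosis 7).
#' @param seed Optional integer seed attached to the condition.
#' @return An object of class `condition_spec`.
#' @examples
#' condition_spec(n = 300, m = 2, k = 5, primary = "high", cross = "low",
#'                rho = 0.6, categories = 4, dist = "normal")
#' @export
condition_spec <- function(n, m, k, primary, cross = "low", rho = 0,
                           categories = 4, dist = "normal", seed = NULL) {
  n <- as.integer(n); m <- as.integer(m); k <- as.integer(k)
  categories <- as.integer(categories)
  stopifnot(n %in% design_levels$n, m %in% design_levels$m,
            k %in% design_levels$k, categories %in% design_levels$categories)
  if (!isTRUE(any(abs(rho - design_levels$rho) < 1e-12))) {
    stop("rho must be one of 0, 0.3, 0.6", call. = FALSE)
  }
  primary <- match.arg(primary, design_levels$primary)
  cross <- match.arg(cross, design_levels$cross)
  dist <- match.arg(dist, design_levels$dist)
  if (m == 1L && rho != 0) {
    stop("single-factor conditions require rho = 0", call. = FALSE)
  }
  structure(list(n = n, m = m, k = k, primary = primary, cross = cross,
                 rho = rho, categories = categories, dist = dist,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf(
    "condition: n=%d m=%d k=%d primary=%s cross=%s rho=%.1f cat=%d dist=%s\n",
    x$n, x$m, x$k, x$primary, x$cross, x$rho, x$categories, x$dist))
  invisible(x)
}

#' Does the underlying continuous distribution deviate from normality?
#' @param cond A `condition_spec`.
#' @return `TRUE` for the `non-normal*` distribution types.
#' @export
is_nonnormal <- function(cond) {
  cond$dist %in% c("non-normal", "non-normal-skewed")
}

#' Are the discretization thresholds asymmetric?
#' @param cond A `condition_spec`.
#' @return `TRUE` for the `*-skewed` distribution types.
#' @export
is_skewed_thresholds <- function(cond) {
  cond$dist %in% c("normal-skewed", "non-normal-skewed")
}

#' Build the full condition grid
#'
#' Crosses all design levels into the complete grid of
#' 3 x 2 x 3 x 3 x 3 x 3 x 4 x 2 = 3,888 conditions. Conditions that are
#' irrelevant by design (one latent factor with a non-zero inter-factor
#' correlation) are flagged in the `excluded` column rather than dropped,
#' so the full crossing stays inspectable; filter with
#' `grid[!grid$excluded, ]` before running.
#'
#' @param overrides Named list restricting any design factor to a subset of
#'   its levels, e.g. `list(n = 300, dist = "normal")`.
#' @return A data frame with one row per condition, a `condition_id`
#'   column, and logical `excluded`.
#' @examples
#' nrow(build_grid())                       # 3888
#' nrow(build_grid(list(n = 300, m = 1)))
#' @export
build_grid <- function(overrides = list()) {
  lv <- design_levels
  for (nm in names(overrides)) {
    if (!nm %in% names(lv)) stop("unknown design factor: ", nm, call. = FALSE)
    keep <- lv[[nm]] %in% overrides[[nm]]
    if (!any(keep)) stop("override leaves no levels for ", nm, call. = FALSE)
    lv[[nm]] <- lv[[nm]][keep]
  }
  grid <- expand.grid(n = lv$n, k = lv$k, m = lv$m, rho = lv$rho,
                      primary = lv$primary, cross = lv$cross,
                      dist = lv$dist, categories = lv$categories,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid$excluded <- grid$m == 1L & grid$rho != 0
  grid$condition_id <- seq_len(nrow(grid))
  grid[, c("condition_id", "n", "m", "k", "primary", "cross", "rho",
           "categories", "dist", "excluded")]
}

#' Turn one grid row into a condition_spec
#' @param row A single-row data frame as produced by [build_grid()].
#' @param seed Optional seed to attach.
#' @return A `condition_spec`.
#' @export
grid_row_to_condition <- function(row, seed = NULL) {
  condition_spec(n = row$n, m = row$m, k = row$k, primary = row$primary,
                 cross = row$cross, rho = row$rho,
                 categories = row$categories, dist = row$dist, seed = seed)
}
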