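#' Discretization thresholds for ordinal item generation
#'
#' Returns the fixed cutpoint sets used to turn continuous scores into 4-
#' or 5-category ordinal items, either symmetric (balanced categories under
#' a standard normal) or positively skewed:
#'
#' * 4 categories, symmetric: (-0.67, 0, 0.67)
#' * 4 categories, skewed: (0, 0.43, 0.97)
#' * 5 categories, symmetric: (-0.84, -0.25, 0.25, 0.84)
#' * 5 categories, skewed: (0.08, 0.25, 0.62, 1.11)
#'
#' @param categories 4 or 5.
#' @param skewed Logical; asymmetric cutpoints if `TRUE`.
#' @return An object of class `threshold_set`: list with `categories`,
#'   `skewed` and the `cutpoints` vector (length `categories - 1`).
#' @export
threshold_table <- function(categories, skewed = FALSE) {
  categories <- as.integer(categories)
  cut <- if (categories == 4L) {
    if (skewed) c(0, 0.43, 0.97) else c(-0.67, 0, 0.67)
  } else if (categories == 5L) {
    if (skewed) c(0.08, 0.25, 0.62, 1.11) else c(-0.84, -0.25, 0.25, 0.84)
  } else {
    stop("unsupported number of categories: ", categories, call. = FALSE)
  }
  structure(list(categories = categories, skewed = isTRUE(skewed),
                 cutpoints = cut),
            class = "threshold_set")
}

#' Sample multivariate normal continuous data
#'
#' @param Sigma Population correlation (or covariance) matrix; must be
#'   positive definite.
#' @param n Number of rows.
#' @param seed Optional integer seed.
#' @return n x p numeric matrix with rows i.i.d. N(0, Sigma).
#' @export
sample_normal <- function(Sigma, n, seed = NULL) {
  Sigma <- as.matrix(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma is not positive definite", call. = FALSE)
  with_seed(seed, MASS::mvrnorm(n, mu = rep(0, ncol(Sigma)), Sigma = Sigma))
}

# Solve the third-order power-polynomial (Fleishman) coefficients (b, c, d)
# with a = -c so that X = a + bZ + cZ^2 + dZ^3, Z ~ N(0,1), has mean 0,
# variance 1, skewness g1 and excess kurtosis g2. Newton iteration with a
# numerical Jacobian from several starts.
fleishman_coef <- function(skew, exkurt) {
  target <- c(1, skew, exkurt)
  moments <- function(th) {
    b <- th[1]; c <- th[2]; d <- th[3]
    v  <- b^2 + 6 * b * d + 2 * c^2 + 15 * d^2
    g1 <- 2 * c * (b^2 + 24 * b * d + 105 * d^2 + 2)
    g2 <- 24 * (b * d + c^2 * (1 + b^2 + 28 * b * d) +
                  d^2 * (12 + 48 * b * d + 141 * c^2 + 225 * d^2))
    c(v, g1, g2)
  }
  starts <- list(c(1, 0.1 * sign(skew + 1e-12), 0.01),
                 c(0.9, 0.25, 0.05), c(0.7, 0.3, 0.1), c(1, 0, 0))
  for (th in starts) {
    for (iter in 1:200) {
      f <- moments(th) - target
      if (max(abs(f)) < 1e-12) break
      J <- matrix(0, 3, 3)
      h <- 1e-7
      for (j in 1:3) {
        thj <- th; thj[j] <- thj[j] + h
        J[, j] <- (moments(thj) - (f + target)) / h
      }
      step <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      # damped update
      th <- th - pmax(pmin(step, 1), -1)
    }
    if (max(abs(moments(th) - target)) < 1e-9) {
      return(c(a = -th[2], b = th[1], c = th[2], d = th[3]))
    }
  }
  stop("infeasible skewness/kurtosis pair (", skew, ", ", exkurt, ")",
       call. = FALSE)
}

# Intermediate (pre-transform) correlation that yields target correlation r
# after applying the same Fleishman transform to both margins.
vm_intermediate <- function(r, cf) {
  b <- cf["b"]; c <- cf["c"]; d <- cf["d"]
  f <- function(rz) {
    rz * (b^2 + 6 * b * d + 9 * d^2) + 2 * c^2 * rz^2 + 6 * d^2 * rz^3 - r
  }
  if (abs(r) < 1e-12) return(0)
  lo <- -1; hi <- 1
  if (f(lo) > 0 || f(hi) < 0) {
    stop("target correlation ", r, " unattainable for these marginal moments",
         call. = FALSE)
  }
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Sample multivariate non-normal continuous data
#'
#' Generates continuous data with population covariance `Sigma` and
#' identical non-normal marginals with the requested skewness and excess
#' kurtosis, by the power-polynomial (Vale-Maurelli) construction: a
#' third-order Fleishman transform is applied to multivariate normal
#' deviates whose intermediate correlations are solved so that the
#' post-transform correlations equal `Sigma`. The contract is moment-level
#' (marginal skewness/kurtosis and the covariance matrix), which is what
#' the downstream polychoric estimators are sensitive to.
#'
#' With `skew = 0` and `exkurt = 0` the transform degenerates to the
#' identity and the generator reduces to [sample_normal()].
#'
#' @param Sigma Population correlation matrix (positive definite).
#' @param n Number of rows.
#' @param skew Target marginal skewness (default 2).
#' @param exkurt Target marginal excess kurtosis (default 7).
#' @param seed Optional integer seed.
#' @return n x p numeric matrix.
#' @export
sample_nonnormal <- function(Sigma, n, skew = 2, exkurt = 7, seed = NULL) {
  Sigma <- as.matrix(Sigma)
  p <- ncol(Sigma)
  cf <- fleishman_coef(skew, exkurt)
  Rz <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      Rz[i, j] <- Rz[j, i] <- vm_intermediate(Sigma[i, j], cf)
    }
  }
  ev <- eigen(Rz, symmetric = TRUE)
  if (min(ev$values) <= 0) { # clip and rescale if the solve left Rz non-PD
    vals <- pmax(ev$values, 1e-6)
    Rz <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    Rz <- stats::cov2cor(Rz)
  }
  Z <- sample_normal(Rz, n, seed = seed)
  cf["a"] + cf["b"] * Z + cf["c"] * Z^2 + cf["d"] * Z^3
}

#' Discretize continuous scores into ordinal categories
#'
#' Assigns category `c` to a score `x` when `t[c-1] < x <= t[c]`, with
#' `t[0] = -Inf` and `t[C] = +Inf`; the mapping is monotone in `x`.
#' Thresholds are applied to the raw continuous scores (unit population
#' variance), so skewed continuous data crossed with symmetric cutpoints
#' still produce skewed observed categories.
#'
#' @param X Continuous numeric matrix (or vector).
#' @param tset A [threshold_table()] result.
#' @param condition Optional `condition_spec` to attach.
#' @return An `ordinal_dataset`: list with integer matrix `values`
#'   (entries in `1..C`), the `threshold_set`, and optionally `condition`
#'   and `truth` (the generating number of factors).
#' @examples
#' d <- discretize(matrix(c(-1, 0, 0.5, 1)), threshold_table(4))
#' d$values[, 1]  # 1 2 3 4
#' @export
discretize <- function(X, tset, condition = NULL) {
  stopifnot(inherits(tset, "threshold_set"))
  X <- as.matrix(X)
  cut <- tset$cutpoints
  if (is.unsorted(cut, strictly = TRUE)) {
    stop("cutpoints must be strictly increasing", call. = FALSE)
  }
  # left.open gives the tau_{c-1} < x <= tau_c convention directly
  codes <- matrix(findInterval(X, cut, left.open = TRUE) + 1L,
                  nrow = nrow(X), ncol = ncol(X))
  colnames(codes) <- if (is.null(colnames(X))) {
    paste0("item", seq_len(ncol(X)))
  } else colnames(X)
  structure(list(values = codes, thresholds = tset, condition = condition,
                 truth = if (is.null(condition)) NULL else condition$m),
            class = "ordinal_dataset")
}

#' @export
print.ordinal_dataset <- function(x, ...) {
  cat(sprintf("ordinal dataset: %d x %d, %d categories (%s)\n",
              nrow(x$values), ncol(x$values), x$thresholds$categories,
              if (x$thresholds$skewed) "skewed" else "symmetric"))
  invisible(x)
}

#' Simulate an ordinal dataset for a condition
#'
#' Full generator: draws a proper population factor model, samples
#' continuous data (normal or non-normal as the condition dictates) with
#' the implied correlation matrix, and discretizes it with the condition's
#' threshold set. A pure function of `(cond, seed)`.
#'
#' @param cond A [condition_spec()].
#' @param seed Integer seed (defaults to `cond$seed`).
#' @return An `ordinal_dataset` with the generating `factor_model`
#'   attached as `$model`.
#' @export
simulate_ordinal <- function(cond, seed = cond$seed) {
  stopifnot(inherits(cond, "condition_spec"))
  fm <- draw_factor_model(cond, seed = derive_seed(seed, 1L))
  tset <- threshold_table(cond$categories, is_skewed_thresholds(cond))
  X <- if (is_nonnormal(cond)) {
    sample_nonnormal(fm$Sigma, cond$n, skew = 2, exkurt = 7,
                     seed = derive_seed(seed, 2L))
  } else {
    sample_normal(fm$Sigma, cond$n, seed = derive_seed(seed, 2L))
  }
  out <- discretize(X, tset, condition = cond)
  out$model <- fm
  out
}
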