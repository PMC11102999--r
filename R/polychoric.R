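#' Bivariate standard-normal CDF
#'
#' Vectorized P(X <= h, Y <= k) for a standard bivariate normal with
#' correlation `rho`, the kernel of the polychoric likelihood.
#'
#' @param h,k Numeric vectors (recycled to common length); `Inf` and
#'   `-Inf` are allowed.
#' @param rho Scalar correlation in (-1, 1).
#' @return Numeric vector of probabilities.
#' @export
bvn_cdf <- function(h, k, rho) {
  stopifnot(length(rho) == 1, abs(rho) < 1)
  nn <- max(length(h), length(k))
  cpp_bvn_cdf(rep_len(as.numeric(h), nn), rep_len(as.numeric(k), nn), rho)
}

# Collapse empty categories and return recoded column plus thresholds.
# Codes are remapped to consecutive 1..C' over the observed categories,
# which is equivalent to merging an empty internal category with its
# adjacent lower neighbour.
recode_column <- function(x) {
  counts <- table(factor(x, levels = sort(unique(x))))
  lev <- as.integer(names(counts))
  if (length(lev) < 2L) {
    stop("degenerate column: a single observed category", call. = FALSE)
  }
  code <- match(x, lev)
  props <- as.numeric(counts) / length(x)
  tau <- qnorm(cumsum(props)[-length(props)])
  list(code = as.integer(code), tau = tau, ncat = length(lev))
}

#' Estimate thresholds of one ordinal column
#'
#' Two-step polychoric estimation fixes each item's thresholds at the
#' standard-normal quantiles of its cumulative category proportions:
#' `tau_c = qnorm(P(X <= c))` for `c = 1..C-1`. Categories with zero
#' observed count are collapsed into the adjacent lower category.
#'
#' @param column Integer vector of ordinal codes.
#' @param C Number of nominal categories; defaults to the largest observed
#'   code. Used only for validation.
#' @return Numeric vector of thresholds (length = observed categories - 1).
#' @examples
#' estimate_thresholds(rep(1:4, each = 25))  # ~ (-0.674, 0, 0.674)
#' @export
estimate_thresholds <- function(column, C = max(column)) {
  if (any(column < 1L) || any(column > C)) {
    stop("codes must lie in 1..C", call. = FALSE)
  }
  recode_column(column)$tau
}

#' Polychoric correlation of one contingency table
#'
#' Two-step maximum likelihood: with the thresholds fixed, the latent
#' correlation maximizes \eqn{\sum_{ij} n_{ij} \log \pi_{ij}(\rho)} where
#' \eqn{\pi_{ij}} is the bivariate-normal rectangle probability of cell
#' (i, j). The one-dimensional likelihood is maximized by Brent search on
#' `[-rho_cap, rho_cap]`; perfectly dependent tables land on the cap and
#' are flagged as boundary solutions.
#'
#' @param table Contingency matrix of counts (rows = categories of item 1).
#' @param tx,ty Threshold vectors of the two items (finite interior
#'   cutpoints; length `nrow(table) - 1` and `ncol(table) - 1`).
#' @param rho_cap Box constraint keeping rectangle probabilities finite.
#' @param tol Brent convergence tolerance.
#' @return List with `rho`, `loglik` and logical `boundary`.
#' @export
estimate_polychoric <- function(table, tx, ty, rho_cap = 0.999, tol = 1e-6) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("negative counts", call. = FALSE)
  if (sum(rowSums(table) > 0) < 2L || sum(colSums(table) > 0) < 2L) {
    stop("all mass on one margin level; correlation undefined",
         call. = FALSE)
  }
  stopifnot(length(tx) == nrow(table) - 1L, length(ty) == ncol(table) - 1L)
  fit <- cpp_poly_pair(matrix(as.integer(table), nrow(table)),
                       as.numeric(tx), as.numeric(ty), rho_cap, tol)
  list(rho = fit$rho, loglik = -fit$negll, boundary = fit$boundary)
}

# Eigenvalue-clipping repair: clip the spectrum below at eps, rebuild, and
# rescale to unit diagonal.
pd_repair <- function(R, eps = 1e-4) {
  ev <- eigen(R, symmetric = TRUE)
  vals <- pmax(ev$values, eps)
  out <- ev$vectors %*% (vals * t(ev$vectors))
  out <- stats::cov2cor(out)
  (out + t(out)) / 2
}

#' Polychoric correlation matrix of an ordinal dataset
#'
#' Assembles all pairwise two-step polychoric estimates into a symmetric
#' unit-diagonal matrix. If the assembled matrix is not positive definite
#' (pairwise estimation does not guarantee joint PD-ness), its spectrum is
#' clipped below at `eps` and the result rescaled to correlation form; the
#' repair is reported in the `repaired` flag.
#'
#' @param data An `ordinal_dataset` or an integer matrix of codes.
#' @param rho_cap,tol Passed to the pairwise estimator.
#' @param eps Eigenvalue floor used by the PD repair.
#' @return An object of class `polychoric_matrix`: list with matrix `R`,
#'   logical `repaired`, data frame `pairwise` (i, j, rho, boundary) and
#'   the per-column `thresholds`.
#' @export
polychoric_matrix <- function(data, rho_cap = 0.999, tol = 1e-6,
                              eps = 1e-4) {
  X <- if (inherits(data, "ordinal_dataset")) data$values else as.matrix(data)
  p <- ncol(X)
  if (p < 2L) stop("need at least two items", call. = FALSE)
  bad <- which(apply(X, 2, function(x) length(unique(x)) < 2L))
  if (length(bad)) {
    stop("degenerate column(s) with a single observed category: ",
         paste(colnames(X)[bad], collapse = ", "), call. = FALSE)
  }
  rec <- lapply(seq_len(p), function(j) recode_column(X[, j]))
  Xr <- vapply(rec, `[[`, integer(nrow(X)), "code")
  fit <- cpp_polychoric_all(Xr, lapply(rec, `[[`, "tau"),
                            vapply(rec, `[[`, 1L, "ncat"), rho_cap, tol)
  R <- fit$R
  dimnames(R) <- list(colnames(X), colnames(X))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  repaired <- FALSE
  if (min(ev) < eps) {
    R <- pd_repair(R, eps)
    dimnames(R) <- list(colnames(X), colnames(X))
    repaired <- TRUE
  }
  ut <- which(upper.tri(fit$R), arr.ind = TRUE)
  structure(list(R = R, repaired = repaired,
                 pairwise = data.frame(i = ut[, 1], j = ut[, 2],
                                       rho = fit$R[ut],
                                       boundary = fit$boundary[ut]),
                 thresholds = lapply(rec, `[[`, "tau")),
            class = "polychoric_matrix")
}

#' @export
print.polychoric_matrix <- function(x, ...) {
  cat(sprintf("polychoric matrix: %d items%s, %d boundary pair(s)\n",
              ncol(x$R), if (x$repaired) " (PD-repaired)" else "",
              sum(x$pairwise$boundary)))
  invisible(x)
}

# Accept either a polychoric_matrix or a plain correlation matrix.
as_corr_matrix <- function(S) {
  if (inherits(S, "polychoric_matrix")) S$R else as.matrix(S)
}
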