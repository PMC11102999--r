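#' Principal-component eigenvalues of a correlation matrix
#'
#' The unreduced spectrum of the correlation matrix itself (principal
#' components, not common factors), sorted descending. The eigenvalues sum
#' to the number of items.
#'
#' @param R Symmetric correlation matrix or `polychoric_matrix`.
#' @return Descending numeric vector of eigenvalues.
#' @export
pca_eigenvalues <- function(R) {
  R <- as_corr_matrix(R)
  if (max(abs(R - t(R))) > 1e-8) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  eigen(R, symmetric = TRUE, only.values = TRUE)$values
}

#' Reference eigenvalues from column-permuted data
#'
#' Builds the random-data reference spectrum of parallel analysis by
#' independently permuting each column of the observed ordinal data
#' (preserving every item's category margins exactly), re-estimating the
#' polychoric matrix of each permuted set, and taking its
#' principal-component eigenvalues. Resampling the observed ordinal
#' margins keeps the reference on the same polychoric footing as the
#' observed spectrum.
#'
#' @param data `ordinal_dataset` or integer matrix of codes.
#' @param n_iter Number of reference sets (default 20).
#' @param seed Optional integer seed.
#' @param max_retries Redraws allowed when a permuted set fails to
#'   estimate.
#' @return List with `mean` and `q95` positionwise reference spectra and
#'   the `n_iter x p` matrix `all`.
#' @export
reference_eigenvalues <- function(data, n_iter = 20L, seed = NULL,
                                  max_retries = 5L) {
  X <- if (inherits(data, "ordinal_dataset")) data$values else as.matrix(data)
  stopifnot(n_iter >= 1L)
  n <- nrow(X); p <- ncol(X)
  with_seed(seed, {
    eigs <- matrix(NA_real_, n_iter, p)
    for (it in seq_len(n_iter)) {
      for (try in seq_len(max_retries + 1L)) {
        Xp <- apply(X, 2, function(col) col[sample.int(n)])
        res <- tryCatch(
          pca_eigenvalues(polychoric_matrix(Xp)),
          error = function(e) NULL)
        if (!is.null(res)) break
      }
      if (is.null(res)) {
        stop("reference iterate failed repeatedly", call. = FALSE)
      }
      eigs[it, ] <- res
    }
    list(mean = colMeans(eigs),
         q95 = apply(eigs, 2, quantile, probs = 0.95, names = FALSE),
         all = eigs)
  })
}

#' Apply the parallel-analysis retention rule
#'
#' Retains the largest `m` such that the observed eigenvalue exceeds the
#' reference eigenvalue at every position `1..m` (sequential stop at the
#' first failure).
#'
#' @param observed Descending observed eigenvalues.
#' @param reference Reference spectrum of the same length (mean or 95th
#'   percentile).
#' @return Integer number of retained factors in `[0, p]`.
#' @examples
#' pa_retain(c(3, 1.5, 0.5), c(1.4, 1.2, 1.05))  # 2
#' @export
pa_retain <- function(observed, reference) {
  stopifnot(length(observed) == length(reference))
  above <- observed > reference
  if (!above[1]) return(0L)
  n <- which(!above)
  if (length(n) == 0L) length(observed) else as.integer(n[1] - 1L)
}

#' Parallel analysis on the polychoric correlation matrix
#'
#' Estimates the number of factors by comparing the principal-component
#' eigenvalues of the observed polychoric matrix against reference
#' eigenvalues from column-permuted data. Factors are retained while the
#' observed eigenvalue exceeds the reference cutoff (mean by default, 95th
#' percentile optionally).
#'
#' @param data `ordinal_dataset` or integer matrix of codes.
#' @param n_iter Number of random reference sets.
#' @param rule Reference cutoff: `"mean"` or `"q95"`.
#' @param seed Optional integer seed for the reference permutations.
#' @return Object of class `pa_result`: list with `n_retained`,
#'   `observed_eigs`, `ref_mean`, `ref_q95` and `rule`.
#' @export
pa_nfactors <- function(data, n_iter = 20L, rule = c("mean", "q95"),
                        seed = NULL) {
  rule <- match.arg(rule)
  obs <- pca_eigenvalues(polychoric_matrix(data))
  ref <- reference_eigenvalues(data, n_iter = n_iter, seed = seed)
  cutoff <- if (rule == "mean") ref$mean else ref$q95
  structure(list(n_retained = pa_retain(obs, cutoff),
                 observed_eigs = obs, ref_mean = ref$mean,
                 ref_q95 = ref$q95, rule = rule, n_iter = n_iter),
            class = "pa_result")
}

#' @export
print.pa_result <- function(x, ...) {
  cat(sprintf("parallel analysis (%s rule, %d iterations): %d factor(s)\n",
              x$rule, x$n_iter, x$n_retained))
  invisible(x)
}
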