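#' Complete a factor model from loadings and factor correlations
#'
#' Given a loading matrix and a factor correlation matrix, computes the
#' unique variances and the implied population correlation matrix of the
#' common-factor decomposition
#' \deqn{\Sigma = \Lambda \Phi \Lambda^{T} + \Psi,}
#' where \eqn{\Psi} is diagonal with entries
#' \eqn{\psi_i = 1 - (\Lambda \Phi \Lambda^T)_{ii}} so that every variable
#' has unit total variance. A draw is *improper* when some communality
#' exceeds 1 (negative unique variance) or the implied matrix is not
#' positive definite; propriety is reported, not raised, so callers can
#' redraw.
#'
#' @param Lambda p x m loading matrix.
#' @param Phi m x m factor correlation matrix (unit diagonal, symmetric).
#' @return An object of class `factor_model` with elements `Lambda`,
#'   `Phi`, `Psi`, `Sigma` and logical `proper`.
#' @examples
#' fm <- build_population_matrix(matrix(0.5, 5, 1), diag(1))
#' fm$Sigma[1, 2]  # 0.25
#' @export
build_population_matrix <- function(Lambda, Phi) {
  Lambda <- as.matrix(Lambda)
  Phi <- as.matrix(Phi)
  stopifnot(all(is.finite(Lambda)), nrow(Phi) == ncol(Phi),
            ncol(Lambda) == nrow(Phi))
  if (max(abs(Phi - t(Phi))) > 1e-10 || any(abs(diag(Phi) - 1) > 1e-10)) {
    stop("Phi must be symmetric with unit diagonal", call. = FALSE)
  }
  common <- Lambda %*% Phi %*% t(Lambda)
  Psi <- 1 - diag(common)
  Sigma <- common
  diag(Sigma) <- 1
  Sigma <- (Sigma + t(Sigma)) / 2
  proper <- all(Psi > 0)
  if (proper) {
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    proper <- min(ev) > 0
  }
  structure(list(Lambda = Lambda, Phi = Phi, Psi = Psi, Sigma = Sigma,
                 proper = proper),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor model: p=%d, m=%d, %s\n", nrow(x$Lambda),
              ncol(x$Lambda), if (x$proper) "proper" else "IMPROPER"))
  invisible(x)
}

# Compound-symmetric factor correlation matrix
phi_matrix <- function(m, rho) {
  Phi <- matrix(rho, m, m)
  diag(Phi) <- 1
  Phi
}

#' Draw a population factor model for a condition
#'
#' Each of the `m * k` items loads on exactly one primary factor, with the
#' loading drawn uniformly from the range of the condition's primary level.
#' When `m > 1`, each item additionally receives one cross-loading, drawn
#' from the cross-level range, on a single designated non-primary factor:
#' the items of factor `f` cross-load on factor `(f mod m) + 1`. Loading
#' every non-primary factor at these ranges would make the strongest
#' multi-factor conditions structurally improper, so a single cyclic
#' placement is used. Factor correlations are compound symmetric at the
#' condition's `rho`.
#'
#' Draws yielding a negative unique variance or a non-PD implied matrix are
#' redrawn up to `max_retries` times; exhausting the budget raises an
#' improper-model error, mirroring the exclusion of infeasible design
#' cells.
#'
#' @param cond A [condition_spec()].
#' @param seed Optional integer seed (defaults to `cond$seed`).
#' @param max_retries Redraw budget for improper draws.
#' @return A proper `factor_model`.
#' @export
draw_factor_model <- function(cond, seed = cond$seed, max_retries = 100L) {
  stopifnot(inherits(cond, "condition_spec"))
  with_seed(seed, {
    p <- cond$m * cond$k
    pr <- loading_range(cond$primary, "primary")
    cr <- loading_range(cond$cross, "cross")
    Phi <- phi_matrix(cond$m, cond$rho)
    for (attempt in seq_len(max_retries + 1L)) {
      Lambda <- matrix(0, p, cond$m)
      for (f in seq_len(cond$m)) {
        rows <- ((f - 1L) * cond$k + 1L):(f * cond$k)
        Lambda[rows, f] <- runif(cond$k, pr[1], pr[2])
        if (cond$m > 1L) {
          target <- (f %% cond$m) + 1L
          Lambda[rows, target] <- runif(cond$k, cr[1], cr[2])
        }
      }
      fm <- build_population_matrix(Lambda, Phi)
      if (fm$proper) return(fm)
    }
    stop("improper factor model after ", max_retries,
         " redraws; condition infeasible", call. = FALSE)
  })
}
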