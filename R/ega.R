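#' EBIC-selected graphical lasso network
#'
#' Fits the graphical lasso over a log-spaced penalty grid running from
#' `lambda_max` (the largest absolute off-diagonal of `S`, at which the
#' estimate is fully sparse) down to `lambda_min_ratio * lambda_max`, and
#' selects the penalty minimizing the Extended Bayesian Information
#' Criterion
#' \deqn{EBIC = -2\ell(K) + E \log n + 4 E \gamma \log p,}
#' with \eqn{\ell(K) = (n/2)(\log\det K - tr(SK))} and `E` the number of
#' nonzero upper-triangle entries of the precision matrix `K`. The network
#' is reported as partial correlations
#' \eqn{W_{ij} = -K_{ij}/\sqrt{K_{ii} K_{jj}}}.
#'
#' @param S Correlation matrix (typically a [polychoric_matrix()]); must
#'   be positive definite.
#' @param n Sample size behind `S` (number of ordinal rows).
#' @param nlambda Grid size (default 100).
#' @param lambda_min_ratio Ratio of smallest to largest penalty.
#' @param gamma EBIC hyperparameter; `gamma = 0` reduces to BIC.
#' @param maxit,tol Coordinate-descent controls.
#' @return Object of class `ggm_network`: list with partial-correlation
#'   matrix `W`, precision `K`, `lambda_selected`, `ebic_value`,
#'   `n_edges`, and the full `lambda_grid` / `ebic_path`.
#' @export
glasso_ebic_select <- function(S, n, nlambda = 100L, lambda_min_ratio = 0.1,
                               gamma = 0.5, maxit = 100L, tol = 1e-4) {
  S <- as_corr_matrix(S)
  p <- ncol(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("S must be positive definite", call. = FALSE)
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax < 1e-10) { # nothing to recover: empty network at any penalty
    W <- K <- diag(1 / diag(S))
    W[] <- 0
    return(structure(list(W = W, K = diag(1 / diag(S)),
                          lambda_selected = NA_real_, ebic_value = NA_real_,
                          n_edges = 0L, lambda_grid = numeric(0),
                          ebic_path = numeric(0)),
                     class = "ggm_network"))
  }
  lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                     length.out = nlambda))
  path <- cpp_glasso_path(S, lambdas, maxit, tol)
  ebic <- rep(NA_real_, nlambda)
  edges <- integer(nlambda)
  for (i in seq_len(nlambda)) {
    if (!path$ok[i]) next # failed grid point: skipped
    K <- path$K[, , i]
    det_ld <- determinant(K, logarithm = TRUE)
    if (det_ld$sign <= 0) next
    ll <- (n / 2) * (as.numeric(det_ld$modulus) - sum(S * K))
    E <- sum(abs(K[upper.tri(K)]) > 1e-8)
    edges[i] <- E
    ebic[i] <- -2 * ll + E * log(n) + 4 * E * gamma * log(p)
  }
  if (all(is.na(ebic))) stop("glasso failed at every grid point",
                             call. = FALSE)
  best <- which.min(ebic)
  K <- path$K[, , best]
  K[abs(K) <= 1e-8] <- 0
  W <- -K / sqrt(diag(K) %o% diag(K))
  diag(W) <- 0
  dimnames(W) <- dimnames(K) <- dimnames(S)
  structure(list(W = W, K = K, lambda_selected = lambdas[best],
                 ebic_value = ebic[best], n_edges = edges[best],
                 lambda_grid = lambdas, ebic_path = ebic,
                 edges_path = edges),
            class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  cat(sprintf("GGM network: %d nodes, %d edges, lambda = %.4g\n",
              ncol(x$W), x$n_edges, x$lambda_selected))
  invisible(x)
}

#' Walktrap communities of a partial-correlation network
#'
#' Runs walktrap (short random-walk agglomeration, modularity-selected
#' cut) on the weighted graph whose edge weights are the absolute partial
#' correlations. Isolated vertices become singleton communities; an empty
#' network therefore yields one community per item.
#'
#' @param net A `ggm_network` or a symmetric weight matrix.
#' @param steps Random-walk length (default 4).
#' @return Integer membership vector (one label per item).
#' @export
detect_communities <- function(net, steps = 4L) {
  W <- if (inherits(net, "ggm_network")) net$W else as.matrix(net)
  A <- abs(W)
  diag(A) <- 0
  p <- ncol(A)
  deg <- rowSums(A)
  connected <- which(deg > 0)
  membership <- integer(p)
  if (length(connected) >= 2L) {
    g <- igraph::graph_from_adjacency_matrix(A[connected, connected,
                                               drop = FALSE],
                                             mode = "undirected",
                                             weighted = TRUE)
    wt <- igraph::cluster_walktrap(g, steps = steps)
    membership[connected] <- as.integer(igraph::membership(wt))
  } else if (length(connected) == 1L) {
    membership[connected] <- 1L
  }
  iso <- which(membership == 0L)
  if (length(iso)) {
    membership[iso] <- max(membership) + seq_along(iso)
  }
  names(membership) <- colnames(W)
  membership
}

# EBIC-glasso with a gamma stepdown: a sparse selection can leave nodes
# with no edges, which community detection would count as spurious
# singleton dimensions. Refit with successively smaller gamma until every
# node is connected; if none of the candidates connects the network, the
# last (least sparse criterion) is returned and singletons stand.
glasso_connected <- function(S, n, nlambda, lambda_min_ratio, gamma,
                             gamma_steps = c(0.25, 0)) {
  gammas <- unique(c(gamma, gamma_steps[gamma_steps < gamma]))
  net <- NULL
  for (g in gammas) {
    net <- glasso_ebic_select(S, n = n, nlambda = nlambda,
                              lambda_min_ratio = lambda_min_ratio,
                              gamma = g)
    if (all(rowSums(abs(net$W)) > 0)) break
  }
  net
}

# Simulated 4-item unidimensional block used by the expand adjustment:
# one factor, population loadings 0.70, normal continuous scores,
# discretized with the supplied threshold set.
simulate_uni_block <- function(n, tset, seed = NULL, k_extra = 4L,
                               loading = 0.70) {
  Sigma <- matrix(loading^2, k_extra, k_extra)
  diag(Sigma) <- 1
  X <- sample_normal(Sigma, n, seed = seed)
  colnames(X) <- paste0("uni_sim", seq_len(k_extra))
  discretize(X, tset)
}

#' Unidimensionality adjustment (expand method)
#'
#' Regularized network models tend to split even one-factor data into
#' multiple communities. The expand adjustment appends a simulated block
#' of 4 items generated from a single factor with population loadings
#' 0.70 (same sample size, independent of the data, discretized with the
#' data's own threshold set), re-runs the network pipeline on the
#' augmented polychoric matrix, and declares the data unidimensional when
#' all original items fall into one community; otherwise the decision is
#' deferred to the standard pipeline on the original items.
#'
#' @param data `ordinal_dataset` (the threshold set is taken from it) or
#'   integer matrix (4-category symmetric thresholds assumed).
#' @param seed Optional integer seed for the simulated block.
#' @param nlambda,lambda_min_ratio,gamma,steps Network-pipeline controls.
#' @return List with `is_unidimensional`, `n_factors` (1 or `NA` when
#'   deferred) and the augmented-network `membership`.
#' @export
unidimensionality_adjust <- function(data, seed = NULL, nlambda = 100L,
                                     lambda_min_ratio = 0.1, gamma = 0.5,
                                     steps = 4L) {
  if (inherits(data, "ordinal_dataset")) {
    X <- data$values
    tset <- data$thresholds
  } else {
    X <- as.matrix(data)
    tset <- threshold_table(4L, FALSE)
  }
  p <- ncol(X)
  block <- simulate_uni_block(nrow(X), tset, seed = seed)
  aug <- cbind(X, block$values)
  S <- polychoric_matrix(aug)
  net <- glasso_connected(S, n = nrow(X), nlambda = nlambda,
                          lambda_min_ratio = lambda_min_ratio,
                          gamma = gamma)
  memb <- detect_communities(net, steps = steps)
  uni <- length(unique(memb[seq_len(p)])) == 1L
  list(is_unidimensional = uni,
       n_factors = if (uni) 1L else NA_integer_,
       membership = memb)
}

#' Louvain unidimensionality check on the zero-order correlation network
#'
#' Applies the Louvain community algorithm to the weighted complete graph
#' whose edge weights are the absolute zero-order (polychoric)
#' correlations. Regularized partial-correlation networks tend to split
#' even one-factor data, whereas on the zero-order network a modularity
#' method merges items whose correlations are near-uniform; data are
#' declared unidimensional when a single community results. With few
#' items per factor and strongly overlapping factors (high inter-factor
#' correlation plus high cross-loadings) the between-block correlations
#' approach the within-block ones and the best split's modularity turns
#' negative, so this check also absorbs such blends into one dimension.
#'
#' @param R Correlation matrix or `polychoric_matrix`.
#' @param seed Optional integer seed (Louvain visits vertices in random
#'   order).
#' @return List with `is_unidimensional` and the Louvain `membership`.
#' @export
louvain_unidimensional <- function(R, seed = NULL) {
  A <- abs(as_corr_matrix(R))
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  memb <- with_seed(seed,
                    igraph::membership(igraph::cluster_louvain(g)))
  list(is_unidimensional = length(unique(memb)) == 1L,
       membership = as.integer(memb))
}

#' Exploratory graph analysis factor count
#'
#' Full EGA pipeline: estimate the polychoric correlation matrix, apply
#' the unidimensionality adjustment, and — when the data are not declared
#' unidimensional — fit the EBIC-selected graphical lasso on the original
#' items and count walktrap communities. The number of factors is the
#' number of distinct communities among the original items.
#'
#' Two unidimensionality adjustments are available: `"louvain"` (default)
#' checks whether the Louvain algorithm finds a single community in the
#' zero-order polychoric network ([louvain_unidimensional()]);
#' `"expand"` appends a simulated unidimensional block and inspects the
#' augmented partial-correlation network
#' ([unidimensionality_adjust()]). `"none"` skips the adjustment.
#'
#' @param data `ordinal_dataset` or integer matrix of codes.
#' @param nlambda,lambda_min_ratio,gamma Penalty-grid and EBIC controls.
#' @param steps Walktrap random-walk length.
#' @param uni_method Unidimensionality adjustment: `"louvain"`,
#'   `"expand"` or `"none"`.
#' @param seed Optional integer seed (Louvain vertex order / simulated
#'   block of the expand method).
#' @return Object of class `ega_result`: list with `n_factors`,
#'   `membership` (`NA` for items left unconnected by the selected
#'   network; such items do not count as dimensions),
#'   `unidimensional_branch` and the fitted `network` (`NULL` when the
#'   adjustment already settled the answer).
#' @export
ega_nfactors <- function(data, nlambda = 100L, lambda_min_ratio = 0.1,
                         gamma = 0.5, steps = 4L,
                         uni_method = c("louvain", "expand", "none"),
                         seed = NULL) {
  uni_method <- match.arg(uni_method)
  X <- if (inherits(data, "ordinal_dataset")) data$values else as.matrix(data)
  n <- nrow(X)
  S <- polychoric_matrix(X)
  uni <- switch(uni_method,
    louvain = louvain_unidimensional(S, seed = seed)$is_unidimensional,
    expand = unidimensionality_adjust(data, seed = seed, nlambda = nlambda,
                                      lambda_min_ratio = lambda_min_ratio,
                                      gamma = gamma,
                                      steps = steps)$is_unidimensional,
    none = FALSE)
  if (uni) {
    return(structure(list(n_factors = 1L,
                          membership = setNames(rep(1L, ncol(X)),
                                                colnames(X)),
                          unidimensional_branch = TRUE, network = NULL),
                     class = "ega_result"))
  }
  net <- glasso_connected(S, n = n, nlambda = nlambda,
                          lambda_min_ratio = lambda_min_ratio,
                          gamma = gamma)
  memb <- detect_communities(net, steps = steps)
  # Items left unconnected even after the gamma stepdown carry no
  # information about dimensional structure: they get NA membership and
  # do not add dimensions. A fully empty network degenerates to one
  # singleton dimension per item.
  connected <- rowSums(abs(net$W)) > 0
  if (any(connected)) {
    memb[!connected] <- NA_integer_
    nf <- length(unique(memb[connected]))
  } else {
    nf <- ncol(X)
  }
  structure(list(n_factors = nf, membership = memb,
                 unidimensional_branch = FALSE, network = net),
            class = "ega_result")
}

#' @export
print.ega_result <- function(x, ...) {
  cat(sprintf("EGA: %d factor(s)%s\n", x$n_factors,
              if (x$unidimensional_branch) " (unidimensionality branch)"
              else ""))
  invisible(x)
}
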