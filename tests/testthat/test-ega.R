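test_that("identity input yields an empty network", {
  net <- glasso_ebic_select(diag(8), n = 500)
  expect_equal(net$n_edges, 0L)
  expect_true(all(net$W == 0))
})

test_that("gamma = 0 reduces the criterion to BIC", {
  d <- make_ordinal(block_sigma(2, 3, 0.5), 400, seed = 51)
  S <- polychoric_matrix(d)
  p <- ncol(S$R)
  # same deterministic lambda grid, so the fitted path is identical and
  # the criteria differ exactly by the 4 * gamma * E * log(p) term
  n0 <- glasso_ebic_select(S, n = 400, gamma = 0, nlambda = 25)
  g5 <- glasso_ebic_select(S, n = 400, gamma = 0.5, nlambda = 25)
  expect_equal(g5$ebic_path,
               n0$ebic_path + 4 * 0.5 * g5$edges_path * log(p),
               tolerance = 1e-8)
})

test_that("selected lambda attains the minimum of the finite EBIC path", {
  d <- make_ordinal(block_sigma(2, 4, 0.45), 500, seed = 52)
  net <- glasso_ebic_select(polychoric_matrix(d), n = 500, nlambda = 40)
  expect_true(all(is.finite(net$ebic_path[!is.na(net$ebic_path)])))
  expect_equal(net$ebic_value, min(net$ebic_path, na.rm = TRUE))
  expect_equal(net$lambda_selected,
               net$lambda_grid[which.min(net$ebic_path)])
})

test_that("partial correlations are bounded and sign-flipped from K", {
  d <- make_ordinal(block_sigma(2, 4, 0.45), 500, seed = 53)
  net <- glasso_ebic_select(polychoric_matrix(d), n = 500)
  expect_true(all(abs(net$W) <= 1))
  off <- upper.tri(net$K)
  nz <- off & abs(net$K) > 0
  expect_true(all(sign(net$W[nz]) == -sign(net$K[nz])))
  expect_equal(diag(net$W), setNames(rep(0, 8), colnames(net$W)))
})

test_that("larger gamma never selects a denser network", {
  for (s in c(61, 62, 63)) {
    d <- make_ordinal(block_sigma(2, 4, 0.4), 300, seed = s)
    S <- polychoric_matrix(d)
    e0 <- glasso_ebic_select(S, n = 300, gamma = 0)$n_edges
    e5 <- glasso_ebic_select(S, n = 300, gamma = 0.5)$n_edges
    e9 <- glasso_ebic_select(S, n = 300, gamma = 1)$n_edges
    expect_lte(e5, e0)
    expect_lte(e9, e5)
  }
})

test_that("p = 2 selection matches a closed-form glasso oracle", {
  # For p = 2 without diagonal penalty the glasso covariance solution is
  # W12 = sign(S12) * max(|S12| - lambda, 0); scan EBIC over the same
  # grid with that closed form and compare the selected estimate.
  for (s12 in c(0.5, 0.25)) {
    S <- matrix(c(1, s12, s12, 1), 2)
    n <- 1000
    net <- glasso_ebic_select(S, n = n)
    lams <- net$lambda_grid
    oracle <- vapply(lams, function(l) {
      w <- sign(s12) * max(abs(s12) - l, 0)
      K <- solve(matrix(c(1, w, w, 1), 2))
      E <- as.integer(abs(K[1, 2]) > 1e-8)
      ll <- (n / 2) * (determinant(K)$modulus[1] - sum(S * K))
      -2 * ll + E * log(n) + 4 * E * 0.5 * log(2)
    }, numeric(1))
    l_star <- lams[which.min(oracle)]
    w_star <- sign(s12) * max(abs(s12) - l_star, 0)
    K_star <- solve(matrix(c(1, w_star, w_star, 1), 2))
    pc_star <- -K_star[1, 2] / sqrt(K_star[1, 1] * K_star[2, 2])
    expect_equal(net$lambda_selected, l_star, tolerance = 1e-10)
    expect_equal(net$W[1, 2], pc_star, tolerance = 1e-4)
  }
})

test_that("walktrap recovers planted blocks and degenerate cases", {
  W <- block_sigma(2, 5, 0.3)
  diag(W) <- 0
  memb <- detect_communities(W)
  expect_equal(length(unique(memb)), 2L)
  expect_equal(length(unique(memb[1:5])), 1L)
  expect_equal(length(unique(memb[6:10])), 1L)
  expect_false(memb[1] == memb[6])

  # empty network: one singleton community per item
  empty <- matrix(0, 4, 4)
  expect_identical(sort(unname(detect_communities(empty))), 1:4)
})

test_that("community membership matches blocks on block-diagonal data", {
  S <- block_sigma(2, 5, 0.49)
  ok <- 0L
  for (s in 1:20) {
    d <- make_ordinal(S, 1000, seed = 700 + s)
    net <- glasso_ebic_select(polychoric_matrix(d), n = 1000)
    memb <- detect_communities(net)
    good <- length(unique(memb[1:5])) == 1L &&
      length(unique(memb[6:10])) == 1L && memb[1] != memb[6]
    ok <- ok + good
  }
  expect_equal(ok, 20L)
})

test_that("four strong orthogonal factors give four communities", {
  cond <- make_cond(n = 1000, m = 4, k = 5, primary = "high",
                    cross = "low", rho = 0)
  hits <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    dat <- simulate_ordinal(cond, seed = 800 + r)
    net <- glasso_ebic_select(polychoric_matrix(dat), n = 1000)
    memb <- detect_communities(net)
    blocks <- split(memb, rep(1:4, each = 5))
    aligned <- all(vapply(blocks, function(b) length(unique(b)) == 1L,
                          logical(1))) &&
      length(unique(vapply(blocks, `[`, integer(1), 1))) == 4L
    hits <- hits + aligned
  }
  expect_gte(hits / reps, 0.95)
})

test_that("expand adjustment separates uni- from multidimensional data", {
  cond1 <- make_cond(n = 1000, m = 1, k = 5, primary = "high", rho = 0)
  uni_hits <- 0L
  for (r in 1:20) {
    dat <- simulate_ordinal(cond1, seed = 1000 + r)
    adj <- unidimensionality_adjust(dat, seed = 2000 + r)
    uni_hits <- uni_hits + adj$is_unidimensional
    expect_equal(length(adj$membership), 5L + 4L)
  }
  expect_gte(uni_hits / 20, 0.95)

  cond2 <- condition_spec(1000, 2, 5, "high", "low", 0, 4, "normal")
  multi_escapes <- 0L
  for (r in 1:20) {
    dat <- simulate_ordinal(cond2, seed = 3000 + r)
    adj <- unidimensionality_adjust(dat, seed = 4000 + r)
    multi_escapes <- multi_escapes + !adj$is_unidimensional
  }
  expect_gte(multi_escapes / 20, 0.95)
})

test_that("louvain check flags unidimensional and spares separable data", {
  cond1 <- make_cond(n = 1000, m = 1, k = 5, primary = "high", rho = 0)
  hits <- 0L
  for (r in 1:20) {
    dat <- simulate_ordinal(cond1, seed = 1100 + r)
    hits <- hits + louvain_unidimensional(polychoric_matrix(dat),
                                          seed = r)$is_unidimensional
  }
  expect_gte(hits / 20, 0.95)

  d2 <- make_ordinal(block_sigma(2, 5, 0.49), 1000, seed = 9)
  expect_false(louvain_unidimensional(polychoric_matrix(d2),
                                      seed = 1)$is_unidimensional)
})

test_that("ega_nfactors recovers strong oblique structures end to end", {
  cond <- condition_spec(300, 2, 10, "high", "low", 0.6, 4, "normal")
  hits <- 0L
  reps <- 20L
  for (r in seq_len(reps)) {
    dat <- simulate_ordinal(cond, seed = 1200 + r)
    res <- ega_nfactors(dat, seed = 1300 + r)
    hits <- hits + (res$n_factors == 2L)
  }
  expect_gte(hits / reps, 0.95)

  # unidimensional data resolve through the adjustment branch
  dat1 <- simulate_ordinal(make_cond(n = 1000, m = 1, k = 5,
                                     primary = "high", rho = 0),
                           seed = 1400)
  res1 <- ega_nfactors(dat1, seed = 1401)
  expect_equal(res1$n_factors, 1L)
  expect_true(res1$unidimensional_branch)

  # independent items, population matrix: empty network degenerates to
  # one singleton dimension per item
  net0 <- glasso_ebic_select(diag(10), n = 400)
  expect_identical(length(unique(detect_communities(net0))), 10L)

  # independent items, finite sample: unconnected items get NA
  # membership and do not add dimensions
  d0 <- make_ordinal(diag(10), 400, seed = 1500)
  res0 <- ega_nfactors(d0, seed = 1501)
  if (any(is.na(res0$membership))) {
    expect_equal(res0$n_factors,
                 length(unique(na.omit(res0$membership))))
  } else {
    expect_equal(res0$n_factors, length(unique(res0$membership)))
  }
})
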