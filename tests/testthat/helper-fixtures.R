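# Shared fixtures: small conditions and datasets built in code.

make_cond <- function(n = 300, m = 2, k = 5, primary = "high",
                      cross = "low", rho = 0.6, categories = 4,
                      dist = "normal") {
  condition_spec(n = n, m = m, k = k, primary = primary, cross = cross,
                 rho = rho, categories = categories, dist = dist)
}

# Ordinal data from an explicit population correlation matrix
make_ordinal <- function(Sigma, n, categories = 4, skewed = FALSE,
                         seed = 1) {
  discretize(sample_normal(Sigma, n, seed = seed),
             threshold_table(categories, skewed))
}

# Block-diagonal correlation matrix: nblock blocks of size bsize with
# within-block correlation r
block_sigma <- function(nblock, bsize, r) {
  one <- matrix(r, bsize, bsize)
  diag(one) <- 1
  S <- diag(nblock * bsize)
  for (b in seq_len(nblock)) {
    idx <- ((b - 1) * bsize + 1):(b * bsize)
    S[idx, idx] <- one
  }
  S
}

# Accuracy (%) of one method over reps on a condition
cell_accuracy <- function(cond, reps, method, seed, id = 1L) {
  r <- run_cell(cond, reps, methods = method, seed = seed,
                condition_id = id)
  evaluate_results(r)$accuracy
}
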