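test_that("the full crossing has 3,888 conditions with the right exclusions", {
  grid <- build_grid()
  expect_equal(nrow(grid), 3888L)
  # one latent factor with non-zero inter-factor correlation is excluded
  expect_true(all(grid$excluded[grid$m == 1 & grid$rho != 0]))
  expect_false(any(grid$excluded[grid$m > 1]))
  expect_false(any(grid$excluded[grid$rho == 0]))
  expect_equal(sum(grid$m == 1 & grid$rho != 0), 864L)

  # overrides restrict to one condition
  one <- build_grid(list(n = 300, k = 5, m = 2, rho = 0.6,
                         primary = "high", cross = "low",
                         dist = "normal", categories = 4))
  expect_equal(nrow(one), 1L)
  expect_error(build_grid(list(n = 123)), "no levels")
  expect_error(build_grid(list(bogus = 1)), "unknown design factor")
})

test_that("run_cell is deterministic and respects reps = 0", {
  cond <- make_cond(n = 300, m = 1, k = 5, primary = "high", rho = 0)
  r1 <- run_cell(cond, 3, methods = "PA", seed = 10, condition_id = 5,
                 pa_args = list(n_iter = 5))
  r2 <- run_cell(cond, 3, methods = "PA", seed = 10, condition_id = 5,
                 pa_args = list(n_iter = 5))
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 3L)
  expect_named(r1, c("condition_id", "n", "m", "k", "primary_level",
                     "cross_level", "rho", "categories", "dist_type",
                     "rep", "method", "estimated", "truth", "correct"))
  r0 <- run_cell(cond, 0, methods = "PA", seed = 10)
  expect_equal(nrow(r0), 0L)
  expect_true(attr(r0, "feasible"))
})

test_that("evaluation arithmetic matches hand counts", {
  r <- data.frame(method = "PA", estimated = c(2L, 2L, 1L), truth = 2L,
                  correct = c(TRUE, TRUE, FALSE))
  ev <- evaluate_results(r)
  expect_equal(ev$accuracy, 200 / 3, tolerance = 1e-10)
  expect_equal(ev$underfactoring, 100 / 3, tolerance = 1e-10)
  expect_equal(ev$overfactoring, 0)

  all_right <- data.frame(method = "EGA", estimated = rep(3L, 4),
                          truth = 3L, correct = TRUE)
  ev2 <- evaluate_results(all_right)
  expect_equal(c(ev2$accuracy, ev2$underfactoring, ev2$overfactoring),
               c(100, 0, 0))

  over <- data.frame(method = "PA", estimated = 3L, truth = 2L,
                     correct = FALSE)
  expect_equal(evaluate_results(over)$overfactoring, 100)

  # missing estimates are incorrect but neither under nor over
  na_mix <- data.frame(method = "PA", estimated = c(NA, 2L), truth = 2L,
                       correct = c(FALSE, TRUE))
  evna <- evaluate_results(na_mix)
  expect_equal(evna$accuracy, 50)
  expect_equal(evna$missing, 50)
  expect_equal(evna$accuracy + evna$underfactoring + evna$overfactoring +
                 evna$missing, 100)
})

test_that("pivot marginals equal weighted cell averages", {
  set.seed(20)
  r <- expand.grid(method = c("PA", "EGA"), n = c(300, 1000),
                   k = c(5L, 10L), categories = c(4L, 5L),
                   dist_type = "normal", m = 2L, rho = 0.6,
                   primary_level = "high", cross_level = "low",
                   rep = 1:10, stringsAsFactors = FALSE)
  r$truth <- r$m
  r$estimated <- ifelse(runif(nrow(r)) < 0.7, r$truth, r$truth - 1L)
  r$correct <- r$estimated == r$truth
  piv <- table1_pivot(r)
  # pivot averages over the two category levels
  cell <- evaluate_results(r[r$method == "PA" & r$n == 300 & r$k == 5, ],
                           by = "method")
  expect_equal(piv$PA_k5_n300[1], cell$accuracy)
  overall <- evaluate_results(r, by = "method")
  agg <- evaluate_results(r, by = c("method", "categories"))
  for (m in c("PA", "EGA")) {
    w <- agg[agg$method == m, ]
    expect_equal(sum(w$accuracy * w$n_reps) / sum(w$n_reps),
                 overall$accuracy[overall$method == m])
  }
})

test_that("logistic summary handles no-effect, degenerate and known-OR cases", {
  set.seed(30)
  half <- data.frame(rep = 1:300, n = rep(c(300, 1000), 150),
                     categories = 4L, truth = 2L)
  half$hit <- runif(300) < 0.6

  # identical outcome vectors for both methods: method OR = 1
  same <- rbind(cbind(half, method = "PA"), cbind(half, method = "EGA"))
  same$estimated <- ifelse(same$hit, 2L, 1L)
  same$correct <- same$estimated == same$truth
  tab <- suppressMessages(logistic_summary(same))
  or_m <- tab$odds_ratio[grepl("^method", tab$term) &
                           !grepl(":", tab$term)]
  expect_equal(unname(or_m), 1, tolerance = 1e-6)

  # single-level factors (categories here) are dropped with a message
  expect_message(logistic_summary(same), "single-level")

  # parameter recovery: generating method log-odds difference of 1
  n_tot <- 10000
  d <- data.frame(method = rep(c("PA", "EGA"), each = n_tot / 2),
                  truth = 2L)
  lp <- ifelse(d$method == "EGA", 0.5, -0.5)
  d$correct <- runif(n_tot) < plogis(lp)
  d$estimated <- ifelse(d$correct, 2L, 1L)
  tab2 <- suppressMessages(logistic_summary(d))
  or2 <- tab2$odds_ratio[tab2$term == "methodPA"]
  expect_gt(1 / or2, 2.4)
  expect_lt(1 / or2, 3.1)
})

test_that("results and ordinal data survive a CSV round trip", {
  cond <- make_cond(n = 300, m = 1, k = 5, primary = "high", rho = 0)
  r <- run_cell(cond, 2, methods = "PA", seed = 2, condition_id = 9,
                pa_args = list(n_iter = 3))
  f <- tempfile(fileext = ".csv")
  write_results(r, f)
  r2 <- read_results(f)
  expect_equal(r2$estimated, r$estimated)
  expect_equal(r2$correct, r$correct)

  d <- simulate_ordinal(cond, seed = 3)
  f2 <- tempfile(fileext = ".csv")
  write_ordinal_csv(d, f2)
  d2 <- read_ordinal_csv(f2, categories = 4)
  expect_identical(d2$values, d$values)
  unlink(c(f, f2))
})
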