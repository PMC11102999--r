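#' Run all replications of one simulation cell
#'
#' For each replication: derives a reproducible seed from the master seed,
#' the condition id and the replication index; simulates an ordinal
#' dataset for the condition; and runs each requested retention method.
#' Estimation failures are caught and recorded as missing estimates (which
#' downstream evaluation counts as incorrect). An infeasible condition
#' (no proper factor model within the redraw budget) returns an empty
#' result flagged `feasible = FALSE`.
#'
#' @param cond A [condition_spec()].
#' @param reps Number of replications.
#' @param methods Character subset of `c("PA", "EGA")`.
#' @param seed Master integer seed.
#' @param condition_id Integer id used in seed derivation and output.
#' @param pa_args,ega_args Extra arguments passed to [pa_nfactors()] /
#'   [ega_nfactors()].
#' @return Data frame with one row per (replication, method):
#'   `condition_id, n, m, k, primary_level, cross_level, rho, categories,
#'   dist_type, rep, method, estimated, truth, correct`. Attribute
#'   `feasible` is `FALSE` for infeasible conditions.
#' @export
run_cell <- function(cond, reps, methods = c("PA", "EGA"), seed = 1L,
                     condition_id = 1L, pa_args = list(),
                     ega_args = list()) {
  stopifnot(inherits(cond, "condition_spec"), reps >= 0L)
  methods <- match.arg(methods, c("PA", "EGA"), several.ok = TRUE)
  rows <- vector("list", reps * length(methods))
  feasible <- TRUE
  ri <- 0L
  for (rep in seq_len(reps)) {
    rep_seed <- derive_seed(seed, condition_id, rep)
    dat <- tryCatch(simulate_ordinal(cond, seed = derive_seed(rep_seed, 1L)),
                    error = function(e) e)
    if (inherits(dat, "error")) {
      if (grepl("infeasible", conditionMessage(dat))) {
        feasible <- FALSE
        break
      }
      dat <- NULL
    }
    for (method in methods) {
      est <- if (is.null(dat)) NA_integer_ else tryCatch({
        if (method == "PA") {
          do.call(pa_nfactors,
                  c(list(data = dat, seed = derive_seed(rep_seed, 2L)),
                    pa_args))$n_retained
        } else {
          do.call(ega_nfactors,
                  c(list(data = dat, seed = derive_seed(rep_seed, 3L)),
                    ega_args))$n_factors
        }
      }, error = function(e) NA_integer_)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        condition_id = condition_id, n = cond$n, m = cond$m, k = cond$k,
        primary_level = cond$primary, cross_level = cond$cross,
        rho = cond$rho, categories = cond$categories, dist_type = cond$dist,
        rep = rep, method = method, estimated = as.integer(est),
        truth = cond$m,
        correct = !is.na(est) && est == cond$m,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (ri == 0L) empty_results() else do.call(rbind, rows[seq_len(ri)])
  attr(out, "feasible") <- feasible
  out
}

empty_results <- function() {
  data.frame(condition_id = integer(0), n = integer(0), m = integer(0),
             k = integer(0), primary_level = character(0),
             cross_level = character(0), rho = numeric(0),
             categories = integer(0), dist_type = character(0),
             rep = integer(0), method = character(0),
             estimated = integer(0), truth = integer(0),
             correct = logical(0), stringsAsFactors = FALSE)
}

#' Run replications over a condition grid
#'
#' Loops [run_cell()] over the non-excluded rows of a grid from
#' [build_grid()]. Each cell's seeds derive from the master seed and the
#' row's `condition_id`, so cells are reproducible independently of which
#' subset is run.
#'
#' @param grid Data frame from [build_grid()] (rows with `excluded = TRUE`
#'   are skipped).
#' @param reps Replications per condition.
#' @param methods Character subset of `c("PA", "EGA")`.
#' @param seed Master seed.
#' @param verbose Print per-cell progress.
#' @param ... Passed to [run_cell()].
#' @return Row-bound per-replication results data frame.
#' @export
run_grid <- function(grid, reps, methods = c("PA", "EGA"), seed = 1L,
                     verbose = FALSE, ...) {
  keep <- if ("excluded" %in% names(grid)) !grid$excluded else
    rep(TRUE, nrow(grid))
  out <- vector("list", sum(keep))
  idx <- 0L
  for (i in which(keep)) {
    cond <- grid_row_to_condition(grid[i, ])
    idx <- idx + 1L
    res <- run_cell(cond, reps, methods = methods, seed = seed,
                    condition_id = grid$condition_id[i], ...)
    if (verbose) {
      message(sprintf("cell %d/%d (id %d): %d rows%s", idx, sum(keep),
                      grid$condition_id[i], nrow(res),
                      if (!attr(res, "feasible")) " [infeasible]" else ""))
    }
    out[[idx]] <- res
  }
  do.call(rbind, out)
}

#' Accuracy, underfactoring and overfactoring summary
#'
#' Per group: accuracy = % of replications with `estimated == truth`;
#' underfactoring = % with `estimated < truth`; overfactoring = % with
#' `estimated > truth`; missing = % with no estimate. Missing estimates
#' count as incorrect but as neither under- nor overfactoring, so the
#' four shares sum to 100.
#'
#' @param results Per-replication results from [run_cell()] /
#'   [run_grid()].
#' @param by Character vector of grouping columns (default `"method"`).
#' @return Data frame with the grouping columns plus `n_reps`,
#'   `accuracy`, `underfactoring`, `overfactoring`, `missing` (percent).
#' @examples
#' r <- data.frame(method = "PA", estimated = c(2, 2, 1), truth = 2,
#'                 correct = c(TRUE, TRUE, FALSE))
#' evaluate_results(r)$accuracy  # 66.7
#' @export
evaluate_results <- function(results, by = "method") {
  stopifnot(nrow(results) > 0, all(by %in% names(results)))
  key <- interaction(results[by], drop = TRUE, lex.order = TRUE)
  parts <- split(results, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    est <- d$estimated
    cbind(d[1, by, drop = FALSE],
          data.frame(
            n_reps = nrow(d),
            accuracy = 100 * mean(!is.na(est) & est == d$truth),
            underfactoring = 100 * mean(!is.na(est) & est < d$truth),
            overfactoring = 100 * mean(!is.na(est) & est > d$truth),
            missing = 100 * mean(is.na(est))))
  }))
  rownames(out) <- NULL
  out
}

#' Accuracy pivot shaped like the study's summary table
#'
#' Mean accuracy (%) per distribution type, number of factors,
#' inter-factor correlation, primary- and cross-loading level, with one
#' column per method x indicators-per-factor x sample-size combination,
#' averaged over the 4- and 5-category variants.
#'
#' @param results Per-replication results.
#' @return Data frame in wide format; columns like `PA_k5_n300`.
#' @export
table1_pivot <- function(results) {
  agg <- evaluate_results(results,
                          by = c("dist_type", "m", "rho", "primary_level",
                                 "cross_level", "method", "k", "n"))
  agg$colname <- sprintf("%s_k%d_n%d", agg$method, agg$k, agg$n)
  wide <- stats::reshape(
    agg[, c("dist_type", "m", "rho", "primary_level", "cross_level",
            "colname", "accuracy")],
    idvar = c("dist_type", "m", "rho", "primary_level", "cross_level"),
    timevar = "colname", direction = "wide")
  names(wide) <- sub("^accuracy\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Logistic-regression effect-size summary
#'
#' Models the probability of a correct retention decision with a
#' binomial-logit GLM containing the retention-method main effect, the
#' main effects of every varying design factor, and all method-by-factor
#' two-way interactions (dummy coding throughout). Design factors with a
#' single observed level are dropped with a message. Coefficients are
#' reported as odds ratios with Wald confidence intervals. Cells at 0% or
#' 100% accuracy can separate the likelihood; `ridge > 0` refits with an
#' L2-penalized logistic model (via glmnet) for stabilized point
#' estimates.
#'
#' @param results Per-replication results with at least two methods.
#' @param ridge Optional ridge penalty (0 = plain ML fit).
#' @return Data frame with `term`, `odds_ratio`, `ci_low`, `ci_high`
#'   (penalized fits report point estimates only) and attribute `fit`.
#' @export
logistic_summary <- function(results, ridge = 0) {
  if (length(unique(results$method)) < 2L) {
    stop("need at least two methods", call. = FALSE)
  }
  d <- results
  d$correct <- as.integer(!is.na(d$estimated) & d$estimated == d$truth)
  d$method <- factor(d$method)
  design <- c("n", "k", "m", "rho", "primary_level", "cross_level",
              "dist_type", "categories")
  design <- design[design %in% names(d)]
  keep <- character(0)
  for (v in design) {
    d[[v]] <- factor(d[[v]])
    if (nlevels(d[[v]]) > 1L) keep <- c(keep, v) else
      message("dropping single-level design factor: ", v)
  }
  if (length(keep) == 0L) {
    form <- correct ~ method
  } else {
    form <- as.formula(paste("correct ~ method *",
                             paste0("(", paste(keep, collapse = " + "), ")")))
  }
  if (ridge > 0) {
    if (!requireNamespace("glmnet", quietly = TRUE)) {
      stop("ridge stabilization requires glmnet", call. = FALSE)
    }
    mm <- stats::model.matrix(form, d)[, -1, drop = FALSE]
    fit <- glmnet::glmnet(mm, d$correct, family = "binomial", alpha = 0,
                          lambda = ridge)
    est <- as.numeric(coef(fit))[-1]
    out <- data.frame(term = colnames(mm), odds_ratio = exp(est),
                      ci_low = NA_real_, ci_high = NA_real_)
  } else {
    fit <- withCallingHandlers(
      glm(form, family = binomial(), data = d),
      warning = function(w) {
        if (grepl("fitted probabilities", conditionMessage(w))) {
          message("note: separation detected (cells at 0%/100%); ",
                  "consider ridge > 0")
          invokeRestart("muffleWarning")
        }
      })
    if (!fit$converged || any(is.na(coef(fit)))) {
      bad <- names(coef(fit))[is.na(coef(fit))]
      if (length(bad)) {
        stop("non-identifiable model; aliased terms: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
    est <- coef(fit)[-1]
    se <- sqrt(diag(vcov(fit)))[-1]
    out <- data.frame(term = names(est), odds_ratio = exp(est),
                      ci_low = exp(est - 1.96 * se),
                      ci_high = exp(est + 1.96 * se))
  }
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' Write / read per-replication results as CSV
#'
#' @param results Per-replication results data frame.
#' @param path File path.
#' @return `read_results` returns the data frame with the schema of
#'   [run_cell()].
#' @export
write_results <- function(results, path) {
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an ordinal dataset as CSV
#'
#' Integer category codes with a header row of item names.
#'
#' @param data An `ordinal_dataset` or integer matrix.
#' @param path File path.
#' @param categories,skewed Threshold set to attach on read.
#' @export
write_ordinal_csv <- function(data, path) {
  X <- if (inherits(data, "ordinal_dataset")) data$values else as.matrix(data)
  write.csv(X, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ordinal_csv
#' @export
read_ordinal_csv <- function(path, categories = 4, skewed = FALSE) {
  X <- as.matrix(read.csv(path, check.names = FALSE))
  storage.mode(X) <- "integer"
  structure(list(values = X,
                 thresholds = threshold_table(categories, skewed),
                 condition = NULL, truth = NULL),
            class = "ordinal_dataset")
}
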