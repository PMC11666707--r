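#' Bootstrap train/validation split
#'
#' Training set: n draws with replacement from the n items.  Validation
#' set: the items never drawn (out-of-bag).  For large n the out-of-bag
#' fraction concentrates near (1 - 1/n)^n, about 36.8%.  If every item is
#' drawn (possible at small n) the split is redrawn with an offset seed,
#' up to 100 attempts.
#'
#' @param items vector of item identifiers (typically pair indices).
#' @param seed integer seed; the same items and seed always give the same
#'   split.
#' @return list with `training` (length n, with repeats) and `validation`
#'   (nonempty, disjoint from the distinct training items).
#' @export
bootstrap_split <- function(items, seed) {
  n <- length(items)
  if (n < 2) stop("need at least 2 items to split", call. = FALSE)
  for (attempt in 0:99) {
    idx <- with_seed(seed + attempt * 10000019, sample.int(n, n, replace = TRUE))
    oob <- setdiff(seq_len(n), unique(idx))
    if (length(oob) > 0)
      return(list(training = items[idx], validation = items[oob],
                  training_idx = idx, validation_idx = oob))
  }
  stop("could not produce a nonempty validation set in 100 attempts",
       call. = FALSE)
}

# y and design rows for one (phenotype, task) combination.  POA uses the
# full host x phage grid; EFF only the pairs with positive EOP.
task_rows <- function(phenotype, task) {
  if (task == "POA") {
    stopifnot(inherits(phenotype, "binary_interaction_matrix"))
    U <- nrow(phenotype); V <- ncol(phenotype)
    list(pairs = cbind(i = rep(seq_len(U), times = V),
                       j = rep(seq_len(V), each = U)),
         y = as.integer(phenotype))
  } else {
    stopifnot(inherits(phenotype, "log_efficiency_table"))
    if (nrow(phenotype) == 0) stop("no positive-EOP pairs for EFF", call. = FALSE)
    list(pairs = cbind(i = phenotype$i, j = phenotype$j),
         y = phenotype$log_eop)
  }
}

#' Bootstrap out-of-bag evaluation of one feature model
#'
#' Runs `n_runs` bootstrap iterations for one task and feature kind.  Each
#' run draws a with-replacement training sample of all eligible pairs
#' (every pair for POA; positive-EOP pairs for EFF), selects the LASSO
#' penalty by `folds`-fold cross-validation on that training sample only,
#' and evaluates on the out-of-bag pairs: classification error at
#' threshold 0.5 for POA, mean absolute error for EFF.  A paired null
#' model (Bernoulli prevalence draw for POA, training mean for EFF) is fit
#' on the same training sample each run.  Run r uses seed
#' `master_seed + r`, so a master seed fixes all runs.
#'
#' If a POA training draw contains a single class it is redrawn with an
#' offset seed (up to 100 attempts).
#'
#' @param host,phage [mutation_profiles()] (post ancestor augmentation).
#' @param phenotype a [binarize()] result (task POA) or a
#'   [log_transform_positive()] result (task EFF).
#' @param kind one of [feature_kinds()].
#' @param task `"POA"` or `"EFF"`.
#' @param n_runs number of bootstrap runs (study protocol: 200).
#' @param master_seed integer master seed.
#' @param folds CV folds per run (default 10).
#' @return object of class `bootstrap_result`: per-run penalties, training
#'   and validation errors for the model and its paired null, the per-run
#'   coefficient matrix (features x runs), intercepts and seeds.
#' @export
run_bootstrap <- function(host, phage, phenotype, kind, task = c("POA", "EFF"),
                          n_runs = 200, master_seed = 1, folds = 10) {
  task <- match.arg(task)
  kind <- match_kind(kind)
  tr <- task_rows(phenotype, task)
  design <- build_design(host, phage, pairs = tr$pairs, kind = kind)
  y <- tr$y
  n <- length(y)
  nf <- length(design$feature_names)
  penalties <- train_error <- val_error <- numeric(n_runs)
  null_train_error <- null_val_error <- numeric(n_runs)
  gammas <- numeric(n_runs)
  coefs <- matrix(0, nf, n_runs, dimnames = list(design$feature_names, NULL))
  seeds <- master_seed + seq_len(n_runs)
  for (r in seq_len(n_runs)) {
    seed_r <- seeds[r]
    split <- bootstrap_split(seq_len(n), seed_r)
    if (task == "POA") {
      attempt <- 0
      while (length(unique(y[split$training_idx])) < 2 && attempt < 100) {
        attempt <- attempt + 1
        split <- bootstrap_split(seq_len(n), seed_r + attempt * 7919)
      }
      if (length(unique(y[split$training_idx])) < 2)
        stop("run ", r, ": could not draw a two-class training sample",
             call. = FALSE)
    }
    ti <- split$training_idx; vi <- split$validation_idx
    sub <- design
    sub$X <- design$X[ti, , drop = FALSE]
    sub$pair_index <- design$pair_index[ti, , drop = FALSE]
    fit <- tryCatch(
      fit_lasso(sub, y[ti], task = task, folds = folds,
                penalty_grid = NULL, seed = seed_r),
      error = function(e) stop("bootstrap run ", r, " failed: ",
                               conditionMessage(e), call. = FALSE))
    vsub <- design
    vsub$X <- design$X[vi, , drop = FALSE]
    vsub$pair_index <- design$pair_index[vi, , drop = FALSE]
    null <- fit_null(task, y[ti])
    if (task == "POA") {
      train_error[r] <- classification_error(y[ti], predict_poa(fit, sub)$class)
      val_error[r] <- classification_error(y[vi], predict_poa(fit, vsub)$class)
      null_train_error[r] <- classification_error(
        y[ti], predict_null(null, length(ti), seed = seed_r + 500000L))
      null_val_error[r] <- classification_error(
        y[vi], predict_null(null, length(vi), seed = seed_r + 600000L))
    } else {
      train_error[r] <- mean_absolute_error(y[ti], predict_eff(fit, sub))
      val_error[r] <- mean_absolute_error(y[vi], predict_eff(fit, vsub))
      null_train_error[r] <- mean_absolute_error(
        y[ti], predict_null(null, length(ti)))
      null_val_error[r] <- mean_absolute_error(
        y[vi], predict_null(null, length(vi)))
    }
    penalties[r] <- fit$penalty
    gammas[r] <- fit$gamma
    coefs[, r] <- fit$coefficients
  }
  structure(list(task = task, kind = kind, n_runs = n_runs,
                 penalties = penalties, train_error = train_error,
                 val_error = val_error, null_train_error = null_train_error,
                 null_val_error = null_val_error, coefs = coefs,
                 gammas = gammas, seeds = seeds,
                 feature_names = design$feature_names,
                 origin = design$origin, master_seed = master_seed,
                 folds = folds),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  metric <- if (x$task == "POA") "classification error" else "MAE"
  cat(sprintf("bootstrap_result: %s / %s, %d runs\n", x$task, x$kind, x$n_runs))
  cat(sprintf("  validation %s: %.4f (model) vs %.4f (null)\n",
              metric, mean(x$val_error), mean(x$null_val_error)))
  invisible(x)
}

#' Paired comparison of two bootstrapped models
#'
#' Two-sided paired Wilcoxon signed-rank test on the per-run validation
#' errors of two bootstrap results that share task, run count and seeds.
#' If every paired difference is zero the p-value is 1 by convention.
#'
#' @param a,b `bootstrap_result` objects paired run-by-run.
#' @return object of class `model_comparison` with the error differences
#'   (a - b), the p-value, and `direction`: which kind had the lower mean
#'   validation error (`"tie"` when equal).
#' @export
compare_models <- function(a, b) {
  stopifnot(inherits(a, "bootstrap_result"), inherits(b, "bootstrap_result"))
  if (a$task != b$task) stop("comparing models of different tasks", call. = FALSE)
  if (a$n_runs != b$n_runs || !identical(a$seeds, b$seeds))
    stop("bootstrap runs are not paired (different run counts or seeds)",
         call. = FALSE)
  if (a$n_runs < 2) stop("need at least 2 paired runs", call. = FALSE)
  d <- a$val_error - b$val_error
  p <- if (all(d == 0)) 1 else
    suppressWarnings(wilcox.test(a$val_error, b$val_error, paired = TRUE,
                                 exact = FALSE)$p.value)
  direction <- if (mean(a$val_error) < mean(b$val_error)) a$kind
               else if (mean(b$val_error) < mean(a$val_error)) b$kind
               else "tie"
  structure(list(kind_a = a$kind, kind_b = b$kind, task = a$task,
                 differences = d, p_value = p, direction = direction,
                 mean_a = mean(a$val_error), mean_b = mean(b$val_error)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("model_comparison (%s): %s (%.4f) vs %s (%.4f), P = %.3g; lower: %s\n",
              x$task, x$kind_a, x$mean_a, x$kind_b, x$mean_b, x$p_value,
              x$direction))
  invisible(x)
}

#' Final model at the bootstrap-averaged penalty
#'
#' Refits one model on all eligible pairs with the penalty fixed to the
#' arithmetic mean of the per-run cross-validated penalties (no CV in this
#' step), as the last stage of the bootstrap protocol.
#'
#' @inheritParams run_bootstrap
#' @param bootstrap the matching `bootstrap_result`.
#' @return a `fitted_model`.
#' @export
fit_final <- function(host, phage, phenotype, bootstrap) {
  stopifnot(inherits(bootstrap, "bootstrap_result"))
  if (bootstrap$n_runs == 0 || length(bootstrap$penalties) == 0)
    stop("empty bootstrap result", call. = FALSE)
  tr <- task_rows(phenotype, bootstrap$task)
  design <- build_design(host, phage, pairs = tr$pairs, kind = bootstrap$kind)
  lam <- mean(bootstrap$penalties)
  fit_lasso(design, tr$y, task = bootstrap$task, folds = bootstrap$folds,
            penalty_grid = lam, seed = bootstrap$master_seed)
}

#' Bootstrap feature-importance table
#'
#' Per feature: the final-model coefficient, the mean of the per-run
#' bootstrap coefficients, the central-90% bootstrap interval (5th and
#' 95th percentiles across runs), and two significance flags:
#' `significant` when that interval excludes 0, and `strict_significant`
#' when even the minimum/maximum bootstrap coefficient does not cross 0.
#' Rows are ranked from most negative to most positive final coefficient.
#'
#' @param final a [fit_final()] model.
#' @param bootstrap the `bootstrap_result` it was derived from.
#' @return data frame of class `importance_table` with columns
#'   `feature_name`, `origin`, `final_coef`, `mean_coef`, `q05`, `q95`,
#'   `min_coef`, `max_coef`, `significant`, `strict_significant`, `rank`,
#'   ordered by rank.
#' @export
feature_importance <- function(final, bootstrap) {
  stopifnot(inherits(final, "fitted_model"),
            inherits(bootstrap, "bootstrap_result"))
  if (!identical(final$feature_names, bootstrap$feature_names))
    stop("feature names of final model and bootstrap do not align",
         call. = FALSE)
  qs <- apply(bootstrap$coefs, 1, quantile, probs = c(0.05, 0.95),
              names = FALSE)
  mn <- apply(bootstrap$coefs, 1, min)
  mx <- apply(bootstrap$coefs, 1, max)
  out <- data.frame(
    feature_name = final$feature_names,
    origin = bootstrap$origin,
    final_coef = unname(final$coefficients),
    mean_coef = unname(rowMeans(bootstrap$coefs)),
    q05 = qs[1, ], q95 = qs[2, ],
    min_coef = mn, max_coef = mx,
    stringsAsFactors = FALSE)
  out$significant <- out$q05 > 0 | out$q95 < 0
  out$strict_significant <- out$min_coef > 0 | out$max_coef < 0
  ord <- order(out$final_coef, out$feature_name)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("importance_table", class(out))
  out
}
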