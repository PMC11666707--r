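# Split a flat named coefficient vector into the blocks the feature kind
# uses (host alpha, phage alpha_tilde, pairwise beta as a sparse N x M
# matrix).  Blocks not belonging to the kind stay NULL.
split_coefficients <- function(coefs, design, host_ids = NULL, phage_ids = NULL) {
  kind <- design$kind
  N <- design$dims[["N"]]; M <- design$dims[["M"]]
  out <- list(alpha = NULL, alpha_tilde = NULL, beta = NULL)
  pos <- 0L
  if (kind %in% c("h", "linear", "mixed")) {
    out$alpha <- coefs[pos + seq_len(N)]
    pos <- pos + N
  }
  if (kind %in% c("p", "linear", "mixed")) {
    out$alpha_tilde <- coefs[pos + seq_len(M)]
    pos <- pos + M
  }
  if (kind %in% c("nonlinear", "mixed")) {
    b <- coefs[pos + seq_len(N * M)]
    nz <- which(b != 0)
    # l-major flat index -> (l, k)
    out$beta <- sparseMatrix(i = (nz - 1L) %/% M + 1L,
                             j = (nz - 1L) %% M + 1L,
                             x = unname(b[nz]), dims = c(N, M))
  }
  out
}

new_fitted_model <- function(task, design, gamma, coefs, penalty,
                             cv_path = NULL, seed = NULL) {
  blocks <- split_coefficients(coefs, design)
  structure(list(task = task, kind = design$kind, gamma = unname(gamma),
                 alpha = blocks$alpha, alpha_tilde = blocks$alpha_tilde,
                 beta = blocks$beta, penalty = unname(penalty),
                 coefficients = coefs, feature_names = design$feature_names,
                 origin = design$origin, dims = design$dims,
                 cv_path = cv_path, seed = seed),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("fitted_model: task %s, kind %s, lambda = %.4g\n",
              x$task, x$kind, x$penalty))
  cat(sprintf("  intercept %.4g; %d of %d coefficients nonzero\n",
              x$gamma, sum(x$coefficients != 0), length(x$coefficients)))
  invisible(x)
}

# Shared CV-LASSO driver.  Penalty grid: when `penalty_grid` is NULL,
# glmnet's standard path of 100 log-spaced values from lambda_max down to
# lambda_max * 1e-4 is used.  The chosen lambda minimizes mean CV loss
# (binomial deviance for POA, MSE for EFF); no one-standard-error rule.
# Folds are a seeded random partition of the rows, unstratified.
fit_lasso <- function(design, y, task, folds, penalty_grid, seed) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  if (length(y) != nrow(X))
    stop("length of response does not match design rows", call. = FALSE)
  if (folds < 2) stop("need at least 2 CV folds", call. = FALSE)
  if (!is.null(penalty_grid)) {
    if (length(penalty_grid) == 0) stop("empty penalty grid", call. = FALSE)
    if (any(penalty_grid < 0)) stop("penalties must be >= 0", call. = FALSE)
    penalty_grid <- sort(unique(penalty_grid), decreasing = TRUE)
  }
  family <- if (task == "POA") "binomial" else "gaussian"
  measure <- if (task == "POA") "deviance" else "mse"
  if (task == "POA" && length(unique(y)) < 2)
    stop("degenerate labels: training response has a single class",
         call. = FALSE)
  if (!is.null(penalty_grid) && length(penalty_grid) == 1) {
    # single requested penalty: no CV to run, fit at that value exactly
    co <- glmnet_at_lambda(X, y, family, penalty_grid)
    coefs <- setNames(as.numeric(co[-1]), design$feature_names)
    return(new_fitted_model(task, design, gamma = co[1], coefs = coefs,
                            penalty = penalty_grid,
                            cv_path = list(lambda = penalty_grid,
                                           cv_loss = NA_real_,
                                           measure = measure),
                            seed = seed))
  }
  cv <- with_seed(seed, {
    foldid <- sample(rep(seq_len(folds), length.out = nrow(X)))
    glmnet::cv.glmnet(X, y, family = family, type.measure = measure,
                      foldid = foldid, lambda = penalty_grid,
                      standardize = FALSE, nlambda = 100L,
                      lambda.min.ratio = 1e-4, thresh = 1e-7, maxit = 1e5)
  })
  lam <- cv$lambda.min
  co <- coef(cv, s = lam)
  coefs <- setNames(as.numeric(co[-1]), design$feature_names)
  new_fitted_model(task, design, gamma = co[1], coefs = coefs, penalty = lam,
                   cv_path = list(lambda = cv$lambda, cv_loss = cv$cvm,
                                  measure = measure),
                   seed = seed)
}

#' Fit the POA model: LASSO logistic regression
#'
#' Models the log-odds of a successful infection as the intercept plus the
#' feature dot product for the design's kind, with an L1 penalty on all
#' coefficients (intercept unpenalized).  The penalty is selected by
#' k-fold cross-validation on the supplied rows only, minimizing mean
#' binomial deviance over a path of 100 log-spaced values from the
#' smallest all-zero penalty down by a factor 1e-4.  Identical inputs and
#' seed give identical fits.
#'
#' @param design a [build_design()] result.
#' @param y binary 0/1 labels, one per design row; both classes must occur.
#' @param folds number of CV folds (default 10).
#' @param penalty_grid optional decreasing positive penalty values
#'   overriding the automatic path.
#' @param seed integer seed controlling the fold assignment.
#' @return A `fitted_model` with `task = "POA"`.
#' @export
fit_lasso_logistic <- function(design, y, folds = 10, penalty_grid = NULL,
                               seed = 1) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("POA labels must be 0/1", call. = FALSE)
  fit_lasso(design, y, task = "POA", folds = folds,
            penalty_grid = penalty_grid, seed = seed)
}

#' Fit the EFF model: LASSO linear regression
#'
#' Models the log efficiency of plating as the intercept plus the feature
#' dot product, minimizing squared error with an L1 penalty (intercept
#' unpenalized); penalty selected by k-fold CV mean squared error.  At a
#' penalty of exactly 0 this reduces to ordinary least squares.
#'
#' @inheritParams fit_lasso_logistic
#' @param y real responses on the log-EOP scale.
#' @return A `fitted_model` with `task = "EFF"`.
#' @export
fit_lasso_linear <- function(design, y, folds = 10, penalty_grid = NULL,
                             seed = 1) {
  fit_lasso(design, as.numeric(y), task = "EFF", folds = folds,
            penalty_grid = penalty_grid, seed = seed)
}

# Coefficients of a LASSO fit at one fixed penalty, no CV.  Fit along a
# short warm-start path ending at the target so the solution at `lambda`
# is as accurate as a path fit, then read off the final point.
glmnet_at_lambda <- function(X, y, family, lambda) {
  init <- glmnet::glmnet(X, y, family = family, standardize = FALSE,
                         nlambda = 30L, lambda.min.ratio = 1e-4,
                         thresh = 1e-9, maxit = 1e6)
  lmax <- max(init$lambda, lambda)
  path <- exp(seq(log(lmax + 1e-12), log(max(lambda, lmax * 1e-8) + 1e-12),
                  length.out = 40L))
  path <- sort(unique(c(path, lambda)), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = family, standardize = FALSE,
                        lambda = path, thresh = 1e-10, maxit = 1e7)
  coef(fit, s = lambda, exact = TRUE, x = X, y = y, family = family,
       standardize = FALSE, thresh = 1e-10, maxit = 1e7)
}

#' Predict presence-or-absence of infection
#'
#' Inverse-logit of the linear predictor gives the infection probability;
#' the class label is 1 when the probability reaches the threshold
#' (default 0.5, matching the symmetric misclassification count used for
#' evaluation).
#'
#' @param model a `fitted_model` with task POA.
#' @param design a [build_design()] result of the same kind and widths.
#' @param threshold probability cutoff in (0, 1); default 0.5.
#' @return list with `probability` and `class` vectors, one per row.
#' @export
predict_poa <- function(model, design, threshold = 0.5) {
  stopifnot(inherits(model, "fitted_model"), model$task == "POA")
  eta <- linear_predictor(model, design)
  p <- plogis(eta)
  list(probability = p, class = as.integer(p >= threshold))
}

#' Predict log efficiency of plating
#'
#' Linear predictor on the log-EOP scale.  Set `exponentiate = TRUE` to
#' export on the EOP scale instead.
#'
#' @param model a `fitted_model` with task EFF.
#' @param design a [build_design()] result of the same kind and widths.
#' @param exponentiate return exp of the predictions (EOP scale)?
#' @return numeric vector, one prediction per design row.
#' @export
predict_eff <- function(model, design, exponentiate = FALSE) {
  stopifnot(inherits(model, "fitted_model"), model$task == "EFF")
  eta <- linear_predictor(model, design)
  if (exponentiate) exp(eta) else eta
}

linear_predictor <- function(model, design) {
  if (ncol(design$X) != length(model$coefficients))
    stop("design width does not match the model's coefficient vector",
         call. = FALSE)
  as.numeric(model$gamma + design$X %*% model$coefficients)
}

#' Null models for POA and EFF
#'
#' The POA null draws predictions from a Bernoulli distribution whose
#' parameter is the maximum-likelihood infection prevalence of the
#' training labels.  The EFF null always predicts the training mean of the
#' log efficiencies.  These are the baselines the fitted models must beat.
#'
#' @param task `"POA"` or `"EFF"`.
#' @param training_labels binary labels (POA) or real log-EOP values (EFF).
#' @return object of class `null_model` with `task` and either `p_hat` or
#'   `mean_value`.
#' @export
fit_null <- function(task = c("POA", "EFF"), training_labels) {
  task <- match.arg(task)
  if (length(training_labels) == 0) stop("empty training labels", call. = FALSE)
  obj <- list(task = task)
  if (task == "POA") {
    y <- as.integer(training_labels)
    if (!all(y %in% c(0L, 1L))) stop("POA labels must be 0/1", call. = FALSE)
    obj$p_hat <- mean(y)
  } else {
    obj$mean_value <- mean(as.numeric(training_labels))
  }
  structure(obj, class = "null_model")
}

#' @rdname fit_null
#' @param null a `null_model`.
#' @param n number of predictions to draw.
#' @param seed integer seed for the Bernoulli draws (POA only).
#' @export
predict_null <- function(null, n, seed = 1) {
  stopifnot(inherits(null, "null_model"))
  if (null$task == "POA")
    with_seed(seed, rbinom(n, 1L, null$p_hat))
  else
    rep(null$mean_value, n)
}

#' Classification error
#'
#' Fraction of mismatched labels, (false positives + false negatives) /
#' number of evaluated pairs.
#'
#' @param truth,predicted equal-length 0/1 vectors.
#' @return error fraction in \[0, 1\].
#' @export
classification_error <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) == 0)
    stop("truth and predictions must be nonempty and of equal length",
         call. = FALSE)
  mean(as.integer(truth) != as.integer(predicted))
}

#' Mean absolute error
#'
#' @param truth,predicted equal-length numeric vectors.
#' @return mean of |truth - predicted|.
#' @export
mean_absolute_error <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) == 0)
    stop("truth and predictions must be nonempty and of equal length",
         call. = FALSE)
  mean(abs(as.numeric(truth) - as.numeric(predicted)))
}

#' Serialize a fitted model to JSON
#'
#' Writes task, kind, intercept, penalty, the nonzero coefficients as a
#' name -> value map, the CV path and the seed.
#'
#' @param model a `fitted_model`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "fitted_model"))
  nz <- model$coefficients[model$coefficients != 0]
  jsonlite::write_json(
    list(task = model$task, kind = model$kind, gamma = model$gamma,
         penalty = model$penalty, coefficients = as.list(nz),
         cv_path = model$cv_path, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
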