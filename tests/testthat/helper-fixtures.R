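# Small in-code fixtures shared across test files.

# Binary profiles with given incidence body; ids generated.
make_profiles <- function(inc, role = "host", prefix = NULL) {
  if (is.null(prefix)) prefix <- if (role == "host") "h_m" else "p_m"
  rownames(inc) <- paste0(substr(role, 1, 1), seq_len(nrow(inc)))
  colnames(inc) <- paste0(prefix, seq_len(ncol(inc)))
  mutation_profiles(inc, role)
}

# Random binary profiles under a fixed seed.
random_profiles <- function(n_strain, n_mut, role = "host", seed = 1,
                            p = 0.4) {
  set.seed(seed)
  make_profiles(matrix(rbinom(n_strain * n_mut, 1, p), n_strain, n_mut),
                role = role)
}

# A fitted_model-like object with hand-set coefficient blocks, for
# prediction tests that need full control.
hand_model <- function(task, kind, gamma, alpha = NULL, alpha_tilde = NULL,
                       beta = NULL, N = length(alpha), M = length(alpha_tilde)) {
  coefs <- c(alpha, alpha_tilde,
             if (!is.null(beta)) as.vector(t(beta)))  # l-major flattening
  structure(list(task = task, kind = kind, gamma = gamma, alpha = alpha,
                 alpha_tilde = alpha_tilde,
                 beta = if (!is.null(beta)) Matrix::Matrix(beta, sparse = TRUE),
                 coefficients = coefs,
                 feature_names = paste0("f", seq_along(coefs)),
                 origin = rep("host", length(coefs)),
                 dims = c(N = N, M = M), penalty = 0),
            class = "fitted_model")
}

# Minimal bootstrap_result for unit tests of downstream consumers.
fake_bootstrap <- function(task = "POA", kind = "linear", val_error,
                           penalties = rep(0.1, length(val_error)),
                           coefs = NULL, feature_names = NULL,
                           seeds = seq_along(val_error)) {
  n <- length(val_error)
  if (is.null(coefs)) {
    feature_names <- feature_names %||% c("h_m1", "p_m1")
    coefs <- matrix(0, length(feature_names), n,
                    dimnames = list(feature_names, NULL))
  }
  structure(list(task = task, kind = kind, n_runs = n, penalties = penalties,
                 train_error = val_error, val_error = val_error,
                 null_train_error = val_error, null_val_error = val_error,
                 coefs = coefs, gammas = rep(0, n), seeds = seeds,
                 feature_names = rownames(coefs),
                 origin = rep("host", nrow(coefs)), master_seed = 0,
                 folds = 10),
            class = "bootstrap_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
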