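#' Feature kinds
#'
#' The five per-pair feature encodings built from host and phage mutation
#' profiles (column counts taken after ancestor augmentation):
#' \describe{
#'   \item{h}{host mutations only; width N.}
#'   \item{p}{phage mutations only; width M.}
#'   \item{linear}{host and phage mutations, additive; width N + M.}
#'   \item{nonlinear}{all host-by-phage mutation products
#'     \eqn{h_{il} p_{jk}}; width N * M.}
#'   \item{mixed}{linear followed by nonlinear; width N + M + N * M.}
#' }
#' @return character vector of the five kind names.
#' @export
feature_kinds <- function() c("h", "p", "linear", "nonlinear", "mixed")

match_kind <- function(kind) {
  kind <- tolower(kind)
  kind <- c(h_only = "h", p_only = "p", h = "h", p = "p", linear = "linear",
            nonlinear = "nonlinear", mixed = "mixed")[kind]
  if (is.na(kind)) stop("unknown feature kind; use one of: ",
                        paste(feature_kinds(), collapse = ", "), call. = FALSE)
  unname(kind)
}

pair_feature_names <- function(host_ids, phage_ids) {
  # l-major, k-minor: host mutation 1 paired with every phage mutation, ...
  paste(rep(host_ids, each = length(phage_ids)),
        rep(phage_ids, times = length(host_ids)), sep = ":")
}

#' Build a per-pair design matrix
#'
#' One row per (host, phage) pair; binary columns drawn from the mutation
#' profiles according to the feature kind.  For `nonlinear` and `mixed`,
#' the pairwise column for host mutation l and phage mutation k holds the
#' product \eqn{h_{il} p_{jk}}, in l-major, k-minor column order.  The bias
#' term is not a column: the fitters carry an unpenalized intercept.
#' Columns are named by mutation id (pairwise terms as `"host:phage"`) so
#' coefficient vectors stay aligned across bootstrap runs; all-zero
#' columns are retained.
#'
#' Features are never standardized: every predictor already lives on the
#' common \{0,1\} scale, which keeps coefficients directly comparable in
#' the importance analysis.
#'
#' @param host,phage [mutation_profiles()] objects (post augmentation).
#' @param pairs two-column integer matrix or data frame of (host row i,
#'   phage column j) indices; defaults to the full U x V grid in
#'   column-major order.
#' @param kind one of [feature_kinds()].
#' @return An object of class `design_matrix`: list with `X` (sparse
#'   dgCMatrix), `kind`, `pair_index` (data frame `i`, `j`),
#'   `feature_names`, `origin` (`"host"`, `"phage"` or `"pair"` per
#'   column), and `dims` (N, M).
#' @export
build_design <- function(host, phage, pairs = NULL, kind = "linear") {
  stopifnot(inherits(host, "mutation_profiles"),
            inherits(phage, "mutation_profiles"))
  kind <- match_kind(kind)
  H <- host$incidence
  P <- phage$incidence
  U <- nrow(H); N <- ncol(H); V <- nrow(P); M <- ncol(P)
  if (is.null(pairs))
    pairs <- cbind(i = rep(seq_len(U), times = V),
                   j = rep(seq_len(V), each = U))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("`pairs` must have two columns (i, j)", call. = FALSE)
  if (any(pairs[, 1] < 1 | pairs[, 1] > U | pairs[, 2] < 1 | pairs[, 2] > V))
    stop("pair index out of range for the given profiles", call. = FALSE)
  Hs <- Matrix(H[pairs[, 1], , drop = FALSE], sparse = TRUE)
  Ps <- Matrix(P[pairs[, 2], , drop = FALSE], sparse = TRUE)
  blocks <- switch(kind,
    h = list(X = Hs, names = colnames(H), origin = rep("host", N)),
    p = list(X = Ps, names = colnames(P), origin = rep("phage", M)),
    linear = list(X = cbind(Hs, Ps),
                  names = c(colnames(H), colnames(P)),
                  origin = c(rep("host", N), rep("phage", M))),
    nonlinear = {
      Xnl <- t(KhatriRao(t(Hs), t(Ps)))  # row r = kron(h_r, p_r): l-major
      list(X = Xnl, names = pair_feature_names(colnames(H), colnames(P)),
           origin = rep("pair", N * M))
    },
    mixed = {
      Xnl <- t(KhatriRao(t(Hs), t(Ps)))
      list(X = cbind(Hs, Ps, Xnl),
           names = c(colnames(H), colnames(P),
                     pair_feature_names(colnames(H), colnames(P))),
           origin = c(rep("host", N), rep("phage", M), rep("pair", N * M)))
    })
  X <- as(as(blocks$X, "CsparseMatrix"), "dMatrix")
  colnames(X) <- blocks$names
  structure(list(X = X, kind = kind,
                 pair_index = data.frame(i = as.integer(pairs[, 1]),
                                         j = as.integer(pairs[, 2])),
                 feature_names = blocks$names, origin = blocks$origin,
                 dims = c(N = N, M = M)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix (kind = %s): %d pairs x %d features, %d nonzero\n",
              x$kind, nrow(x$X), ncol(x$X), length(x$X@x)))
  invisible(x)
}

#' Export a design matrix as sparse triplets
#'
#' Debug export: one line per nonzero entry, columns `row`, `feature_name`,
#' `value`, tab separated.
#'
#' @param design a [build_design()] result.
#' @param path output TSV path.
#' @export
write_design_triplets <- function(design, path) {
  stopifnot(inherits(design, "design_matrix"))
  Xt <- as(design$X, "TsparseMatrix")
  df <- data.frame(row = Xt@i + 1L,
                   feature_name = design$feature_names[Xt@j + 1L],
                   value = Xt@x)
  df <- df[order(df$row, Xt@j), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Evaluate a fitted model over the full host x phage grid
#'
#' Matrix-form evaluation of the linear predictor
#' \deqn{\Phi_{ij} = \gamma + \sum_l \alpha_l h_{il} + \sum_k
#'   \tilde\alpha_k p_{jk} + \sum_{l,k} \beta_{lk} h_{il} p_{jk}}
#' with the terms absent from the model's feature kind dropped.  Equivalent
#' to building the per-pair design for all U x V pairs and taking dot
#' products with the coefficient vector, but computed as
#' \eqn{\gamma + H\alpha \mathbf{1}^T + \mathbf{1}(P\tilde\alpha)^T +
#' H B P^T}.
#'
#' @param model a `fitted_model` from [fit_lasso_logistic()],
#'   [fit_lasso_linear()] or [fit_final()].
#' @param host,phage the [mutation_profiles()] the model was trained on
#'   (same mutation columns, any strains).
#' @return An object of class `prediction_surface`: list with `task`,
#'   `kind` and `values`, a U x V matrix on the linear-predictor scale
#'   (log-odds for POA, log-EOP for EFF).
#' @export
predict_surface <- function(model, host, phage) {
  stopifnot(inherits(model, "fitted_model"))
  H <- host$incidence
  P <- phage$incidence
  U <- nrow(H); V <- nrow(P)
  phi <- matrix(model$gamma, U, V, dimnames = list(rownames(H), rownames(P)))
  if (!is.null(model$alpha)) {
    if (length(model$alpha) != ncol(H))
      stop("host coefficient length does not match profile width", call. = FALSE)
    phi <- phi + as.vector(H %*% model$alpha) %*% t(rep(1, V))
  }
  if (!is.null(model$alpha_tilde)) {
    if (length(model$alpha_tilde) != ncol(P))
      stop("phage coefficient length does not match profile width", call. = FALSE)
    phi <- phi + rep(1, U) %*% t(as.vector(P %*% model$alpha_tilde))
  }
  if (!is.null(model$beta)) {
    if (!all(dim(model$beta) == c(ncol(H), ncol(P))))
      stop("pairwise coefficient dimensions do not match profiles", call. = FALSE)
    phi <- phi + as.matrix(H %*% model$beta %*% Matrix::t(Matrix(P, sparse = TRUE)))
  }
  structure(list(task = model$task, kind = model$kind, values = phi),
            class = "prediction_surface")
}

#' @export
print.prediction_surface <- function(x, ...) {
  cat(sprintf("prediction_surface (%s, kind = %s): %d x %d, range [%.3g, %.3g]\n",
              x$task, x$kind, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}
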