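#' Efficiency of plating from plaque counts
#'
#' EOP of phage j on host i from a dilution-series plaque assay:
#' \deqn{e_{ij} = (q_{ij} / q_{anc,j}) \cdot d^{\,s_{ij} - s_{anc,j}}}
#' where `q` are plaque counts, `s` the number of dilution steps performed
#' before counting, and `d` the dilution ratio (5 in the original assay
#' design).  An EOP of 1 means the phage plates as efficiently on the test
#' host as on the ancestral host; 0 means no plaques at any dilution.
#'
#' Vectorized over `q`, `s`, `q_anc`, `s_anc`.
#'
#' @param q plaque count(s) on the test host, nonnegative integer.
#' @param q_anc plaque count(s) on the ancestral host, strictly positive.
#' @param s,s_anc dilution steps for the test and ancestral assays.
#' @param d dilution ratio, positive; default 5.
#' @return nonnegative EOP value(s).
#' @export
compute_eop <- function(q, q_anc, s, s_anc, d = 5) {
  if (any(d <= 0)) stop("dilution ratio d must be positive", call. = FALSE)
  if (any(q_anc <= 0))
    stop("ancestor reference produced no plaques (q_anc = 0); EOP undefined",
         call. = FALSE)
  if (any(q < 0) || any(s < 0) || any(s_anc < 0))
    stop("counts and dilution steps must be >= 0", call. = FALSE)
  if (any(q != round(q)) || any(q_anc != round(q_anc)))
    stop("plaque counts must be integers", call. = FALSE)
  (q / q_anc) * d^(s - s_anc)
}

#' Read plaque-assay tables and assemble an EOP matrix
#'
#' `path` is a CSV with columns `host_id, phage_id, q, s` (one row per
#' assayed pair); `ancestor_path` a CSV with columns `phage_id, q_anc,
#' s_anc` giving each phage's reference assay on the ancestral host.
#' Every (host, phage) combination in `path` must be present exactly once.
#'
#' @param path pairwise plaque-count CSV.
#' @param ancestor_path ancestor-reference CSV.
#' @param d dilution ratio (default 5).
#' @return A [cross_infection_matrix()] with hosts and phages in first
#'   order of appearance.
#' @export
eop_matrix_from_plaques <- function(path, ancestor_path, d = 5) {
  pairs <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  anc <- read.csv(ancestor_path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("host_id", "phage_id", "q", "s")
  if (!all(req %in% names(pairs)))
    stop("plaque table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!all(c("phage_id", "q_anc", "s_anc") %in% names(anc)))
    stop("ancestor table must have columns: phage_id, q_anc, s_anc",
         call. = FALSE)
  miss <- setdiff(pairs$phage_id, anc$phage_id)
  if (length(miss) > 0)
    stop("no ancestor reference for phage(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  m <- merge(pairs, anc, by = "phage_id", sort = FALSE)
  m$eop <- compute_eop(m$q, m$q_anc, m$s, m$s_anc, d = d)
  hosts <- unique(pairs$host_id)
  phages <- unique(pairs$phage_id)
  eop <- matrix(NA_real_, length(hosts), length(phages),
                dimnames = list(hosts, phages))
  idx <- cbind(match(m$host_id, hosts), match(m$phage_id, phages))
  if (anyDuplicated(idx))
    stop("duplicate plaque-assay row for a (host, phage) pair", call. = FALSE)
  eop[idx] <- m$eop
  cross_infection_matrix(eop)
}

#' Binarize EOP into presence-or-absence of infection
#'
#' POA label per pair: \eqn{d_{ij} = 1} exactly when \eqn{e_{ij} > 0}
#' (strict), 0 otherwise.  Zero EOP is treated as an exact zero, never an
#' epsilon.
#'
#' @param x a [cross_infection_matrix()].
#' @return An object of class `binary_interaction_matrix`: a 0/1 integer
#'   matrix with the same dimnames.
#' @export
binarize <- function(x) {
  stopifnot(inherits(x, "cross_infection_matrix"))
  labels <- matrix(as.integer(x$eop > 0), nrow(x$eop),
                   dimnames = dimnames(x$eop))
  structure(labels, class = c("binary_interaction_matrix", class(labels)))
}

#' Log-transform the positive EOP values
#'
#' The efficiency phenotype is modeled on the natural-log scale,
#' \eqn{e'_{ij} = \ln e_{ij}}, and only where infection occurs
#' (\eqn{e_{ij} > 0}).  Zero-EOP pairs are excluded, not imputed: the log
#' is undefined there and the efficiency model is fit only on susceptible
#' hosts.
#'
#' @param x a [cross_infection_matrix()].
#' @return data frame of class `log_efficiency_table` with columns
#'   `host_id`, `phage_id`, `i`, `j` (row/column index into the matrix) and
#'   `log_eop`; zero rows when no pair is positive.
#' @export
log_transform_positive <- function(x) {
  stopifnot(inherits(x, "cross_infection_matrix"))
  idx <- which(x$eop > 0, arr.ind = TRUE)
  out <- data.frame(
    host_id = rownames(x$eop)[idx[, 1]],
    phage_id = colnames(x$eop)[idx[, 2]],
    i = as.integer(idx[, 1]),
    j = as.integer(idx[, 2]),
    log_eop = log(x$eop[idx]),
    stringsAsFactors = FALSE)
  out <- out[order(out$j, out$i), , drop = FALSE]  # column-major, stable
  rownames(out) <- NULL
  class(out) <- c("log_efficiency_table", class(out))
  out
}

#' Shapiro-Wilk normality diagnostic for log-EOP values
#'
#' Reports how close the log-efficiency distribution is to Gaussian.  The
#' result is diagnostic only -- it is logged alongside the analysis and
#' never gates the pipeline, since the linear model does not require exact
#' normality to be useful.
#'
#' @param table a [log_transform_positive()] result, or a numeric vector.
#' @return list with elements `W` (statistic in (0, 1]), `p_value`, `n`.
#' @export
test_log_normality <- function(table) {
  values <- if (is.data.frame(table)) table$log_eop else as.numeric(table)
  if (length(values) < 3)
    stop("Shapiro-Wilk requires at least 3 values, got ", length(values),
         call. = FALSE)
  if (length(values) > 5000) values <- values[seq_len(5000)]
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p_value = sw$p.value, n = length(values))
}
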