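#' Construct a cross-infection (EOP) matrix
#'
#' A U x V grid of efficiency-of-plating values: entry `[i, j]` is the EOP
#' of phage `j` on host `i`, a dimensionless nonnegative efficiency relative
#' to the ancestral host.  Zero means the phage cannot infect that host.
#'
#' @param eop numeric matrix, hosts in rows, phages in columns; all entries
#'   finite and >= 0.  Rownames are host ids, colnames phage ids.
#' @param host_ids,phage_ids optional label vectors overriding dimnames.
#' @return An object of class `cross_infection_matrix` wrapping the matrix.
#' @export
cross_infection_matrix <- function(eop, host_ids = NULL, phage_ids = NULL) {
  eop <- as.matrix(eop)
  if (!is.null(host_ids)) rownames(eop) <- host_ids
  if (!is.null(phage_ids)) colnames(eop) <- phage_ids
  if (is.null(rownames(eop)) || is.null(colnames(eop)))
    stop("host and phage ids are required", call. = FALSE)
  if (anyNA(eop)) {
    idx <- which(is.na(eop), arr.ind = TRUE)[1, ]
    stop(sprintf("missing EOP cell at host '%s', phage '%s'",
                 rownames(eop)[idx[1]], colnames(eop)[idx[2]]), call. = FALSE)
  }
  if (any(eop < 0)) {
    idx <- which(eop < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative EOP (%g) at host '%s', phage '%s'",
                 eop[idx[1], idx[2]], rownames(eop)[idx[1]],
                 colnames(eop)[idx[2]]), call. = FALSE)
  }
  storage.mode(eop) <- "double"
  structure(list(eop = eop), class = "cross_infection_matrix")
}

#' @export
print.cross_infection_matrix <- function(x, ...) {
  e <- x$eop
  cat(sprintf("cross_infection_matrix: %d hosts x %d phages (%d cells)\n",
              nrow(e), ncol(e), length(e)))
  cat(sprintf("  positive (EOP > 0): %d; zero: %d; max EOP %.3g\n",
              sum(e > 0), sum(e == 0), max(e)))
  invisible(x)
}

#' @export
dim.cross_infection_matrix <- function(x) dim(x$eop)

#' Read a cross-infection CSV
#'
#' Layout: header row of phage ids, first column of host ids, body of
#' nonnegative decimals.  Every cell must be present.
#'
#' @param path path to a CSV file.
#' @return A [cross_infection_matrix()] object.
#' @export
read_cross_infection <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, header = TRUE, check.names = FALSE, row.names = NULL)
  host_ids <- as.character(df[[1]])
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(body) <- "double")
  rownames(body) <- host_ids
  cross_infection_matrix(body)
}

#' Write a cross-infection CSV
#'
#' @param x a [cross_infection_matrix()] object.
#' @param path output path.
#' @export
write_cross_infection <- function(x, path) {
  stopifnot(inherits(x, "cross_infection_matrix"))
  df <- data.frame(host_id = rownames(x$eop), x$eop, check.names = FALSE)
  write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
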