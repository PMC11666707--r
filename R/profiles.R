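#' Construct a mutation-profile table
#'
#' A mutation profile is a binary strain-by-mutation incidence matrix: entry
#' `[i, l]` is 1 when strain `i` carries mutation `l` relative to the common
#' ancestor and 0 otherwise.  Host profiles are U strains by N mutations,
#' phage profiles V by M.
#'
#' @param incidence numeric matrix of 0/1 entries; rownames are strain ids,
#'   colnames are mutation ids (both may instead be supplied via the
#'   `strain_ids` / `mutation_ids` arguments).
#' @param role `"host"` or `"phage"`.
#' @param strain_ids,mutation_ids optional character vectors overriding the
#'   dimnames of `incidence`.
#' @param mutation_meta optional data frame of per-mutation annotation with
#'   columns `mutation_id`, `position_bp` (1-based), `gene`, `type`.
#' @return An object of class `mutation_profiles`: a list with elements
#'   `incidence` (integer matrix with dimnames), `role`, and optionally
#'   `mutation_meta`.
#' @seealso [read_mutation_profiles()], [augment_ancestor()]
#' @export
mutation_profiles <- function(incidence, role = c("host", "phage"),
                              strain_ids = NULL, mutation_ids = NULL,
                              mutation_meta = NULL) {
  role <- match.arg(role)
  incidence <- as.matrix(incidence)
  if (!is.null(strain_ids)) rownames(incidence) <- strain_ids
  if (!is.null(mutation_ids)) colnames(incidence) <- mutation_ids
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("strain and mutation ids are required", call. = FALSE)
  bad <- which(!(incidence == 0 | incidence == 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "non-binary incidence entry at strain '%s', mutation '%s'",
      rownames(incidence)[bad[1, 1]], colnames(incidence)[bad[1, 2]]),
      call. = FALSE)
  if (anyDuplicated(rownames(incidence)))
    stop("duplicate strain id: ",
         rownames(incidence)[duplicated(rownames(incidence))][1],
         call. = FALSE)
  if (anyDuplicated(colnames(incidence)))
    stop("duplicate mutation id: ",
         colnames(incidence)[duplicated(colnames(incidence))][1],
         call. = FALSE)
  storage.mode(incidence) <- "integer"
  obj <- list(incidence = incidence, role = role)
  if (!is.null(mutation_meta)) {
    req <- c("mutation_id", "position_bp", "gene", "type")
    if (!all(req %in% names(mutation_meta)))
      stop("mutation_meta must have columns: ",
           paste(req, collapse = ", "), call. = FALSE)
    obj$mutation_meta <- as.data.frame(mutation_meta)
  }
  class(obj) <- "mutation_profiles"
  obj
}

#' @export
print.mutation_profiles <- function(x, ...) {
  cat(sprintf("mutation_profiles (%s): %d strains x %d mutations\n",
              x$role, nrow(x$incidence), ncol(x$incidence)))
  cat(sprintf("  mutations carried per strain: %.1f (mean), range [%d, %d]\n",
              mean(rowSums(x$incidence)), min(rowSums(x$incidence)),
              max(rowSums(x$incidence))))
  invisible(x)
}

#' @export
dim.mutation_profiles <- function(x) dim(x$incidence)

#' Read a mutation-profile TSV
#'
#' Expected layout: one header row of mutation ids, a leading column of
#' strain ids, and a body of 0/1 tokens, tab separated.  Row and column
#' order is preserved.  The strain-label convention "day-isolate" (e.g.
#' `"22-3"`) is parsed into an `isolation_day` attribute when every evolved
#' label matches it, but is never required: the inference itself makes no
#' use of time.
#'
#' @param path path to a TSV file.
#' @param role `"host"` or `"phage"`.
#' @return A [mutation_profiles()] object.
#' @export
read_mutation_profiles <- function(path, role = c("host", "phage")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", row.names = NULL)
  if (ncol(df) < 2) stop("profile table needs a strain column and at least one mutation column",
                         call. = FALSE)
  header <- colnames(df)[-1]
  if (anyDuplicated(header))
    stop("duplicate mutation id: ", header[duplicated(header)][1],
         " in ", path, call. = FALSE)
  strain_ids <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(body %in% c("0", "1")), arr.ind = TRUE)
  if (length(bad) > 0) {
    bad <- matrix(bad, ncol = 2)
    stop(sprintf("malformed token '%s' at strain '%s', mutation '%s' in %s",
                 body[bad[1, 1], bad[1, 2]], strain_ids[bad[1, 1]],
                 colnames(body)[bad[1, 2]], path), call. = FALSE)
  }
  inc <- matrix(as.integer(body), nrow = nrow(body),
                dimnames = list(strain_ids, colnames(body)))
  prof <- mutation_profiles(inc, role = role)
  day <- suppressWarnings(as.integer(sub("-.*$", "", strain_ids)))
  if (all(!is.na(day) | strain_ids %in% c("anc", "ancestor")))
    attr(prof, "isolation_day") <- day
  prof
}

#' Write a mutation-profile TSV
#'
#' Inverse of [read_mutation_profiles()]: writing then reading reproduces
#' the incidence matrix, ids, and ordering exactly.
#'
#' @param profiles a [mutation_profiles()] object.
#' @param path output path.
#' @export
write_mutation_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "mutation_profiles"))
  df <- data.frame(strain_id = rownames(profiles$incidence),
                   profiles$incidence, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Append the artificial ancestor trait
#'
#' Adds one indicator column carried by the ancestral strain only: value 1
#' in the ancestor row and 0 in every other row.  This places the ancestor
#' inside the feature space so it can appear in the cross-infection matrix
#' alongside evolved strains.  Applied independently to host and phage
#' tables; the mutation count N (or M) increases by one.
#'
#' @param profiles a [mutation_profiles()] object.
#' @param ancestor_id strain label of the ancestor; must be present.
#' @param column_id name for the new column (default `"ancestor"`).
#' @return The augmented `mutation_profiles` object.
#' @export
augment_ancestor <- function(profiles, ancestor_id, column_id = "ancestor") {
  stopifnot(inherits(profiles, "mutation_profiles"))
  inc <- profiles$incidence
  if (!ancestor_id %in% rownames(inc))
    stop("ancestor strain not found: ", ancestor_id, call. = FALSE)
  if (column_id %in% colnames(inc))
    stop("profiles already carry a column named '", column_id,
         "'; ancestor augmentation applied twice?", call. = FALSE)
  newcol <- as.integer(rownames(inc) == ancestor_id)
  inc <- cbind(inc, newcol)
  colnames(inc)[ncol(inc)] <- column_id
  out <- profiles
  out$incidence <- inc
  out$ancestor_id <- ancestor_id
  out
}

#' Read a per-mutation annotation table
#'
#' Companion TSV keyed by mutation id with columns `mutation_id`,
#' `position_bp` (1-based genome coordinate), `gene`, `type`.  Annotation
#' is display-only: inference never touches it.
#'
#' @param path path to the TSV.
#' @return data frame with the four columns above.
#' @export
read_mutation_annotations <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  req <- c("mutation_id", "position_bp", "gene", "type")
  if (!all(req %in% names(df)))
    stop("annotation table must have columns: ",
         paste(req, collapse = ", "), call. = FALSE)
  df$position_bp <- as.integer(df$position_bp)
  df
}
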