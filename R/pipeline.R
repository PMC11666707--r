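#' Full analysis pipeline
#'
#' Drives the complete workflow from input files (or a synthetic
#' scenario) to a report bundle on disk: phenotype transforms, bootstrap
#' evaluation of the requested feature kinds for the requested tasks,
#' pairwise model comparisons, final fits at the bootstrap-averaged
#' penalty, feature-importance tables and predicted phenotype matrices.
#'
#' `config` is a named list (e.g. read from a YAML/JSON file by the
#' caller) with entries:
#' \describe{
#'   \item{host_profiles, phage_profiles}{paths to mutation-profile TSVs;
#'     or}
#'   \item{scenario}{a [synthetic_scenario()] or preset name, used when no
#'     profile paths are given.}
#'   \item{eop_matrix}{path to a precomputed EOP CSV.}
#'   \item{plaque_table, ancestor_table}{paths to raw plaque-assay CSVs
#'     (used when no `eop_matrix` is given; if both are supplied the
#'     precomputed matrix wins and a warning is issued).}
#'   \item{dilution_ratio}{for plaque tables; default 5.}
#'   \item{host_ancestor, phage_ancestor}{ancestor strain ids; when given,
#'     [augment_ancestor()] is applied to file-based profiles.}
#'   \item{tasks}{subset of `c("POA", "EFF")`; default both.}
#'   \item{kinds}{subset of [feature_kinds()]; default all five.}
#'   \item{n_runs}{bootstrap runs (default 200).}
#'   \item{folds}{CV folds (default 10).}
#'   \item{seed}{master seed (default 1).}
#' }
#'
#' @param config named list as above.
#' @param out_dir output directory for the report bundle.
#' @return invisibly, a list with the in-memory results (`bootstraps`,
#'   `comparisons`, `finals`, `importance`, `phenotypes`, `normality`).
#' @export
run_full_analysis <- function(config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tasks <- toupper(config$tasks %||% c("POA", "EFF"))
  kinds <- vapply(config$kinds %||% feature_kinds(), match_kind, "")
  n_runs <- config$n_runs %||% 200
  folds <- config$folds %||% 10
  seed <- config$seed %||% 1

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$host_profiles)) {
    host <- read_mutation_profiles(config$host_profiles, "host")
    phage <- read_mutation_profiles(config$phage_profiles, "phage")
    if (!is.null(config$host_ancestor))
      host <- augment_ancestor(host, config$host_ancestor)
    if (!is.null(config$phage_ancestor))
      phage <- augment_ancestor(phage, config$phage_ancestor)
  } else {
    sc <- config$scenario %||% "small"
    if (is.character(sc)) sc <- synthetic_scenario(sc)
    sc$seed <- config$seed %||% sc$seed
    prof <- generate_profiles(sc)
    host <- prof$host; phage <- prof$phage
    truth <- generate_truth(host, phage, sc)
  }
  if (!is.null(config$eop_matrix)) {
    if (!is.null(config$plaque_table))
      warning("both a precomputed EOP matrix and raw plaque tables were ",
              "supplied; using the precomputed matrix", call. = FALSE)
    eop <- read_cross_infection(config$eop_matrix)
  } else if (!is.null(config$plaque_table)) {
    eop <- eop_matrix_from_plaques(config$plaque_table,
                                   config$ancestor_table,
                                   d = config$dilution_ratio %||% 5)
  } else if (exists("truth", inherits = FALSE)) {
    eop <- generate_phenotypes(host, phage, truth, sc)
  } else {
    stop("config must provide an EOP matrix, plaque tables, or a synthetic ",
         "scenario", call. = FALSE)
  }
  if (nrow(eop$eop) != nrow(host$incidence) ||
      ncol(eop$eop) != nrow(phage$incidence))
    stop("EOP matrix dimensions do not match the profile tables", call. = FALSE)

  # --- phenotypes ---------------------------------------------------------
  poa <- binarize(eop)
  logeff <- log_transform_positive(eop)
  normality <- if (nrow(logeff) >= 3) test_log_normality(logeff) else NULL

  bundle <- list(bootstraps = list(), comparisons = list(), finals = list(),
                 importance = list(), phenotypes = list(poa = poa,
                                                        log_eff = logeff),
                 normality = normality)

  for (task in tasks) {
    phen <- if (task == "POA") poa else logeff
    if (task == "EFF" && nrow(logeff) == 0) next
    boots <- list()
    for (kind in kinds) {
      key <- paste(task, kind, sep = "_")
      boots[[kind]] <- run_bootstrap(host, phage, phen, kind, task,
                                     n_runs = n_runs, master_seed = seed,
                                     folds = folds)
      bundle$bootstraps[[key]] <- boots[[kind]]
      jsonlite::write_json(
        list(task = task, kind = kind, n_runs = n_runs, seed = seed,
             penalties = boots[[kind]]$penalties,
             train_error = boots[[kind]]$train_error,
             val_error = boots[[kind]]$val_error,
             null_train_error = boots[[kind]]$null_train_error,
             null_val_error = boots[[kind]]$null_val_error),
        file.path(out_dir, paste0("errors_", key, ".json")),
        auto_unbox = TRUE, digits = NA)
      final <- fit_final(host, phage, phen, boots[[kind]])
      bundle$finals[[key]] <- final
      imp <- feature_importance(final, boots[[kind]])
      bundle$importance[[key]] <- imp
      write.table(imp, file.path(out_dir, paste0("importance_", key, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(
        data.frame(feature_name = final$feature_names,
                   origin = final$origin,
                   coefficient = unname(final$coefficients)),
        file.path(out_dir, paste0("coefficients_", key, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      surf <- predict_surface(final, host, phage)
      pred <- if (task == "POA")
        matrix(as.integer(plogis(surf$values) >= 0.5), nrow(surf$values),
               dimnames = dimnames(surf$values))
      else surf$values
      df <- data.frame(host_id = rownames(pred), pred, check.names = FALSE)
      write.csv(df, file.path(out_dir, paste0("predicted_", key, ".csv")),
                quote = FALSE, row.names = FALSE)
    }
    if (length(boots) >= 2) {
      cmb <- utils::combn(names(boots), 2)
      comp <- data.frame(kind_a = cmb[1, ], kind_b = cmb[2, ],
                         p_value = NA_real_, direction = NA_character_,
                         mean_error_a = NA_real_, mean_error_b = NA_real_)
      for (q in seq_len(ncol(cmb))) {
        cc <- compare_models(boots[[cmb[1, q]]], boots[[cmb[2, q]]])
        comp$p_value[q] <- cc$p_value
        comp$direction[q] <- cc$direction
        comp$mean_error_a[q] <- cc$mean_a
        comp$mean_error_b[q] <- cc$mean_b
      }
      bundle$comparisons[[task]] <- comp
      write.table(comp, file.path(out_dir, paste0("comparisons_", task, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  summary <- list(
    n_hosts = nrow(host$incidence), n_phages = nrow(phage$incidence),
    n_host_mutations = ncol(host$incidence),
    n_phage_mutations = ncol(phage$incidence),
    n_pairs = length(eop$eop), n_positive = sum(eop$eop > 0),
    n_zero = sum(eop$eop == 0),
    shapiro_wilk = normality, tasks = tasks, kinds = kinds,
    n_runs = n_runs, folds = folds, seed = seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(bundle)
}
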