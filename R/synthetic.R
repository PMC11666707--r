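#' Synthetic coevolution scenario
#'
#' Parameter set for the synthetic-data generator.  Defaults (and the
#' `toy` / `small` / `study-shaped` presets) emulate the structure of a
#' serial-transfer phage-bacteria coevolution experiment: strains sampled
#' at successive checkpoints accumulate mutations along nested lineages,
#' a sparse set of planted driver mutations shifts infection probability
#' and efficiency, host drivers are biased negative (resistance) and
#' phage drivers positive (host-range expansion), and efficiencies carry
#' Gaussian noise on the log scale, giving a right-skewed EOP
#' distribution with a long tail.
#'
#' @param name preset: `"toy"` (6 hosts x 5 phages), `"small"` (30 x 30),
#'   `"study-shaped"` (51 x 45 with 18 host and 176 phage mutation sites,
#'   mirroring the dimensions of the original study), or `"custom"`.
#' @param U,V total strain counts including the ancestors.
#' @param N,M numbers of candidate mutation sites (pre-augmentation).
#' @param n_days sampling checkpoints.
#' @param mutation_rate_per_day expected new mutations per lineage per
#'   checkpoint (hosts; phages use `phage_mutation_rate_per_day`).
#' @param phage_mutation_rate_per_day phage rate; defaults to the host rate.
#' @param n_host_drivers,n_phage_drivers planted nonzero coefficients.
#' @param effect_scale magnitude of planted coefficients (logit units for
#'   POA, log-EOP units for EFF).
#' @param host_sign_bias probability a planted host coefficient is
#'   negative; `phage_sign_bias` the probability a phage one is positive.
#' @param noise_sd Gaussian noise s.d. on log EOP.
#' @param target_prevalence grid-mean infection probability the POA
#'   intercept is calibrated to (ignored when `gamma_poa` is given).
#' @param gamma_poa,gamma_eff optional fixed intercepts.
#' @param seed integer seed.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(name = c("custom", "toy", "small", "study-shaped"),
                               U = 30, V = 30, N = 24, M = 30, n_days = 6,
                               mutation_rate_per_day = 1,
                               phage_mutation_rate_per_day = NULL,
                               n_host_drivers = 5, n_phage_drivers = 5,
                               effect_scale = 2, host_sign_bias = 0.7,
                               phage_sign_bias = 0.7, noise_sd = 0.3,
                               target_prevalence = 0.4, gamma_poa = NULL,
                               gamma_eff = 0, seed = 1) {
  name <- match.arg(name)
  preset <- switch(name,
    toy = list(U = 6, V = 5, N = 4, M = 6, n_days = 3,
               n_host_drivers = 2, n_phage_drivers = 2),
    small = list(U = 30, V = 30, N = 24, M = 30, n_days = 6,
                 n_host_drivers = 5, n_phage_drivers = 5),
    `study-shaped` = list(U = 51, V = 45, N = 18, M = 176, n_days = 10,
                          mutation_rate_per_day = 0.4,
                          phage_mutation_rate_per_day = 3,
                          n_host_drivers = 5, n_phage_drivers = 10),
    custom = list())
  sc <- list(name = name, U = U, V = V, N = N, M = M, n_days = n_days,
             mutation_rate_per_day = mutation_rate_per_day,
             phage_mutation_rate_per_day = phage_mutation_rate_per_day,
             n_host_drivers = n_host_drivers,
             n_phage_drivers = n_phage_drivers,
             effect_scale = effect_scale, host_sign_bias = host_sign_bias,
             phage_sign_bias = phage_sign_bias, noise_sd = noise_sd,
             target_prevalence = target_prevalence, gamma_poa = gamma_poa,
             gamma_eff = gamma_eff, seed = seed)
  sc[names(preset)] <- preset
  if (is.null(sc$phage_mutation_rate_per_day))
    sc$phage_mutation_rate_per_day <- sc$mutation_rate_per_day
  stopifnot(sc$U > 1, sc$V > 1, sc$N > 0, sc$M > 0, sc$n_days > 0,
            sc$n_host_drivers <= sc$N, sc$n_phage_drivers <= sc$M,
            sc$host_sign_bias >= 0, sc$host_sign_bias <= 1,
            sc$phage_sign_bias >= 0, sc$phage_sign_bias <= 1,
            sc$noise_sd >= 0)
  class(sc) <- "synthetic_scenario"
  sc
}

# One population's nested profiles: strains sampled at checkpoints, each
# descending from a uniformly chosen earlier strain (or the ancestor) and
# adding Poisson-many new mutations at sites the parent does not yet
# carry.  Sites can be hit independently in different lineages (parallel
# evolution), as repeatedly observed for the loci targeted in phage-host
# coevolution.
simulate_lineages <- function(n_strains, n_sites, n_days, rate) {
  n_evolved <- n_strains - 1L
  days <- sort(rep(seq_len(n_days), length.out = n_evolved))
  genotypes <- vector("list", n_evolved)
  ids <- character(n_evolved)
  isolate_no <- integer(n_days)
  for (s in seq_len(n_evolved)) {
    d <- days[s]
    earlier <- which(days[seq_len(s - 1L)] <= d)
    pick <- sample.int(length(earlier) + 1L, 1L)  # +1 slot = ancestor
    if (pick > length(earlier)) {
      parent <- integer(0); pd <- 0L
    } else {
      parent <- genotypes[[earlier[pick]]]; pd <- days[earlier[pick]]
    }
    n_new <- rpois(1L, rate * max(d - pd, 1L))
    free <- setdiff(seq_len(n_sites), parent)
    n_new <- min(n_new, length(free))
    new_sites <- if (n_new > 0) free[sample.int(length(free), n_new)] else integer(0)
    genotypes[[s]] <- sort(c(parent, new_sites))
    isolate_no[d] <- isolate_no[d] + 1L
    ids[s] <- paste0(d, "-", isolate_no[d])
  }
  inc <- matrix(0L, n_strains, n_sites,
                dimnames = list(c("anc", ids),
                                paste0("m", seq_len(n_sites))))
  for (s in seq_len(n_evolved)) inc[s + 1L, genotypes[[s]]] <- 1L
  inc
}

#' Generate nested host and phage mutation profiles
#'
#' Simulates branching lineages over `n_days` checkpoints for both
#' populations: each sampled strain inherits its parent's mutations and
#' adds new Poisson-distributed ones at previously unhit sites, so
#' profiles are temporally nested.  Each table includes an all-zero
#' ancestor strain (`"anc"`) and is returned with the artificial ancestor
#' trait already appended via [augment_ancestor()].
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `host` and `phage` [mutation_profiles()].
#' @export
generate_profiles <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  with_seed(scenario$seed, {
    h <- simulate_lineages(scenario$U, scenario$N, scenario$n_days,
                           scenario$mutation_rate_per_day)
    colnames(h) <- paste0("h_", colnames(h))
    p <- simulate_lineages(scenario$V, scenario$M, scenario$n_days,
                           scenario$phage_mutation_rate_per_day)
    colnames(p) <- paste0("p_", colnames(p))
    list(host = augment_ancestor(mutation_profiles(h, "host"), "anc"),
         phage = augment_ancestor(mutation_profiles(p, "phage"), "anc"))
  })
}

# Drivers are planted on identifiable segregating sites: strain frequency
# in [0.15, 0.85] (a fixed or absent site carries no signal) and an
# incidence pattern unique within the table (a site perfectly linked to a
# passenger is not attributable to either locus by any method).  When too
# few sites qualify, the constraints are relaxed in that order.
pick_drivers <- function(incidence, n_drivers) {
  freq <- colMeans(incidence)
  pat <- apply(incidence, 2, paste, collapse = "")
  unique_pat <- !(duplicated(pat) | duplicated(pat, fromLast = TRUE))
  segregating <- freq >= 0.15 & freq <= 0.85
  good <- which(segregating & unique_pat)
  if (length(good) < n_drivers) good <- which(unique_pat & freq > 0 & freq < 1)
  if (length(good) >= n_drivers)
    return(sort(good[sample.int(length(good), n_drivers)]))
  ord <- order(abs(freq - 0.5))
  sort(ord[seq_len(min(n_drivers, length(ord)))])
}

#' Planted ground-truth models
#'
#' Draws sparse planted coefficients over the generated profiles: driver
#' positions shared between the POA (logit-scale) and EFF (log-EOP-scale)
#' truths, signs drawn with the scenario's asymmetric biases (host
#' drivers predominantly negative, phage drivers predominantly positive),
#' magnitudes equal to `effect_scale`.  The POA intercept is calibrated so
#' the grid-mean infection probability equals `target_prevalence`, unless
#' `gamma_poa` is fixed in the scenario.  The ancestor-trait columns carry
#' no planted effect.
#'
#' @param host,phage profiles from [generate_profiles()].
#' @param scenario the same [synthetic_scenario()].
#' @return list of class `ground_truth` with `poa` and `eff`
#'   `fitted_model`-like truth models (kind `"linear"`), plus
#'   `host_drivers` / `phage_drivers` (named coefficient vectors of the
#'   planted nonzero effects) and the scenario.
#' @export
generate_truth <- function(host, phage, scenario) {
  H <- host$incidence; P <- phage$incidence
  with_seed(scenario$seed + 1L, {
    hd <- pick_drivers(H[, colnames(H) != "ancestor", drop = FALSE],
                       scenario$n_host_drivers)
    pd <- pick_drivers(P[, colnames(P) != "ancestor", drop = FALSE],
                       scenario$n_phage_drivers)
    alpha <- setNames(numeric(ncol(H)), colnames(H))
    alpha_tilde <- setNames(numeric(ncol(P)), colnames(P))
    hsign <- ifelse(runif(length(hd)) < scenario$host_sign_bias, -1, 1)
    psign <- ifelse(runif(length(pd)) < scenario$phage_sign_bias, 1, -1)
    alpha[hd] <- hsign * scenario$effect_scale
    alpha_tilde[pd] <- psign * scenario$effect_scale
    raw <- as.vector(H %*% alpha) %*% t(rep(1, nrow(P))) +
      rep(1, nrow(H)) %*% t(as.vector(P %*% alpha_tilde))
    gamma_poa <- scenario$gamma_poa
    if (is.null(gamma_poa)) {
      f <- function(g) mean(plogis(g + raw)) - scenario$target_prevalence
      gamma_poa <- uniroot(f, c(-50, 50))$root
    }
    mk <- function(task, gamma) structure(
      list(task = task, kind = "linear", gamma = gamma, alpha = alpha,
           alpha_tilde = alpha_tilde, beta = NULL,
           coefficients = c(alpha, alpha_tilde),
           feature_names = c(names(alpha), names(alpha_tilde)),
           origin = c(rep("host", length(alpha)),
                      rep("phage", length(alpha_tilde))),
           dims = c(N = ncol(H), M = ncol(P)), penalty = 0),
      class = "fitted_model")
    structure(list(poa = mk("POA", gamma_poa),
                   eff = mk("EFF", scenario$gamma_eff),
                   host_drivers = alpha[hd], phage_drivers = alpha_tilde[pd],
                   scenario = scenario),
              class = "ground_truth")
  })
}

#' Generate a cross-infection matrix from a planted truth
#'
#' For each (host, phage) pair: infection occurs with probability
#' inverse-logit of the POA truth's linear predictor; where it occurs,
#' log EOP is the EFF truth's linear predictor plus Gaussian noise and
#' EOP = exp(log EOP); where it does not, EOP = 0.  The resulting EOP
#' distribution is right-skewed (lognormal-like) with a long tail.
#'
#' @param host,phage profiles from [generate_profiles()].
#' @param truth a [generate_truth()] result.
#' @param scenario the [synthetic_scenario()].
#' @return a [cross_infection_matrix()].
#' @export
generate_phenotypes <- function(host, phage, truth, scenario) {
  stopifnot(inherits(truth, "ground_truth"))
  phi_poa <- predict_surface(truth$poa, host, phage)$values
  phi_eff <- predict_surface(truth$eff, host, phage)$values
  with_seed(scenario$seed + 2L, {
    prob <- plogis(phi_poa)
    poa <- matrix(rbinom(length(prob), 1L, prob), nrow(prob))
    eprime <- phi_eff + matrix(rnorm(length(prob), 0, scenario$noise_sd),
                               nrow(prob))
    eop <- ifelse(poa == 1L, exp(eprime), 0)
    dimnames(eop) <- dimnames(phi_poa)
    cross_infection_matrix(eop)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: profiles, planted truth and phenotypes in one
#' call.
#'
#' @param scenario a [synthetic_scenario()] (or preset name).
#' @param seed optional seed overriding the scenario's.
#' @return list with `host`, `phage`, `truth`, `eop`
#'   (a [cross_infection_matrix()]) and `scenario`.
#' @export
generate_dataset <- function(scenario = "small", seed = NULL) {
  if (is.character(scenario)) scenario <- synthetic_scenario(scenario)
  if (!is.null(seed)) scenario$seed <- seed
  prof <- generate_profiles(scenario)
  truth <- generate_truth(prof$host, prof$phage, scenario)
  eop <- generate_phenotypes(prof$host, prof$phage, truth, scenario)
  list(host = prof$host, phage = prof$phage, truth = truth, eop = eop,
       scenario = scenario)
}

#' Write a named synthetic fixture to disk
#'
#' Generates a dataset for one of the presets and writes the host and
#' phage profile TSVs, the EOP CSV and a ground-truth JSON into `dir`.
#' The same name and seed always produce byte-identical files.
#'
#' @param name `"toy"`, `"small"` or `"study-shaped"`.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return invisibly, a named vector of the file paths written.
#' @export
make_fixture <- function(name = c("toy", "small", "study-shaped"),
                         dir = ".", seed = 1) {
  name <- match.arg(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ds <- generate_dataset(synthetic_scenario(name), seed = seed)
  paths <- c(
    host = file.path(dir, paste0(name, "_host_profiles.tsv")),
    phage = file.path(dir, paste0(name, "_phage_profiles.tsv")),
    eop = file.path(dir, paste0(name, "_eop.csv")),
    truth = file.path(dir, paste0(name, "_truth.json")))
  write_mutation_profiles(ds$host, paths[["host"]])
  write_mutation_profiles(ds$phage, paths[["phage"]])
  write_cross_infection(ds$eop, paths[["eop"]])
  tr <- ds$truth
  beta_list <- list()
  jsonlite::write_json(
    list(kind = tr$poa$kind,
         gamma = list(poa = tr$poa$gamma, eff = tr$eff$gamma),
         alpha = as.list(tr$poa$alpha[tr$poa$alpha != 0]),
         alpha_tilde = as.list(tr$poa$alpha_tilde[tr$poa$alpha_tilde != 0]),
         beta = beta_list,
         scenario = unclass(ds$scenario)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
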