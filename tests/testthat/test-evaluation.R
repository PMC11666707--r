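test_that("bootstrap splits are deterministic, out-of-bag, and exhaustive at n = 2", {
  s1 <- bootstrap_split(1:10, seed = 5)
  s2 <- bootstrap_split(1:10, seed = 5)
  expect_identical(s1, s2)
  expect_length(s1$training, 10)
  expect_true(length(s1$validation) > 0)
  expect_length(intersect(unique(s1$training), s1$validation), 0)

  # n = 2: whenever both draws coincide, validation is the other item
  for (seed in 1:50) {
    sp <- bootstrap_split(c("a", "b"), seed)
    expect_setequal(c(unique(sp$training), sp$validation), c("a", "b"))
  }
  expect_error(bootstrap_split(1, seed = 1), "at least 2")
})

test_that("bootstrap evaluation honors its contracts on a toy dataset", {
  ds <- generate_dataset("toy", seed = 3)
  poa <- binarize(ds$eop)
  b <- run_bootstrap(ds$host, ds$phage, poa, "linear", "POA",
                     n_runs = 2, master_seed = 7)
  expect_equal(b$n_runs, 2)
  expect_true(all(b$val_error >= 0 & b$val_error <= 1))
  expect_true(all(b$train_error >= 0 & b$train_error <= 1))
  expect_true(all(b$penalties > 0))
  expect_equal(dim(b$coefs), c(length(b$feature_names), 2))

  b2 <- run_bootstrap(ds$host, ds$phage, poa, "linear", "POA",
                      n_runs = 2, master_seed = 7)
  expect_identical(b$penalties, b2$penalties)
  expect_identical(b$coefs, b2$coefs)
  expect_identical(b$val_error, b2$val_error)
})

test_that("EFF bootstrap uses only positive-EOP pairs", {
  ds <- generate_dataset("toy", seed = 3)
  tab <- log_transform_positive(ds$eop)
  b <- suppressWarnings(
    run_bootstrap(ds$host, ds$phage, tab, "linear", "EFF",
                  n_runs = 2, master_seed = 1, folds = 5))
  expect_true(all(is.finite(b$val_error)))
  expect_true(all(b$val_error >= 0))
})

test_that("paired model comparison is symmetric and sensitive to a constant shift", {
  a <- fake_bootstrap(val_error = rep(0.3, 10))
  expect_equal(compare_models(a, a)$p_value, 1)

  set.seed(1)
  errs <- runif(200, 0.2, 0.4)
  a <- fake_bootstrap(val_error = errs)
  b <- fake_bootstrap(kind = "h", val_error = errs + 0.1)
  cab <- compare_models(a, b)
  cba <- compare_models(b, a)
  expect_lt(cab$p_value, 1e-6)
  expect_identical(cab$direction, "linear")
  expect_equal(cab$p_value, cba$p_value)
  expect_identical(cba$direction, "linear")
  expect_equal(cba$differences, -cab$differences)

  expect_error(compare_models(fake_bootstrap(val_error = 0.5),
                              fake_bootstrap(val_error = 0.4)),
               "at least 2")
  expect_error(
    compare_models(a, fake_bootstrap(val_error = errs[1:100])),
    "not paired")
})

test_that("the final penalty is the arithmetic mean of the per-run penalties", {
  ds <- generate_dataset("toy", seed = 3)
  poa <- binarize(ds$eop)
  b <- run_bootstrap(ds$host, ds$phage, poa, "linear", "POA",
                     n_runs = 2, master_seed = 7)
  b$penalties <- c(0.1, 0.3)
  fin <- fit_final(ds$host, ds$phage, poa, b)
  expect_equal(fin$penalty, 0.2)

  b$penalties <- c(0.25, 0.25)
  expect_equal(fit_final(ds$host, ds$phage, poa, b)$penalty, 0.25)
})

test_that("importance intervals and flags follow the bootstrap coefficients", {
  coefs <- rbind(h_m1 = rep(0, 20),          # zero in every run
                 p_m1 = seq(0.5, 2, length.out = 20),  # positive in all runs
                 p_m2 = c(rep(-1, 19), 0.2)) # crosses zero only at the max
  b <- fake_bootstrap(val_error = rep(0.2, 20), coefs = coefs)
  final <- hand_model("POA", "linear", 0,
                      alpha = c(h_m1 = 0),
                      alpha_tilde = c(p_m1 = 1.2, p_m2 = -0.8))
  final$feature_names <- rownames(coefs)
  imp <- feature_importance(final, b)
  z <- imp[imp$feature_name == "h_m1", ]
  expect_equal(c(z$q05, z$q95), c(0, 0))
  expect_false(z$significant)
  pos <- imp[imp$feature_name == "p_m1", ]
  expect_gt(pos$q05, 0)
  expect_true(pos$significant)
  expect_true(pos$strict_significant)
  mixed <- imp[imp$feature_name == "p_m2", ]
  expect_true(mixed$significant)        # central 90% excludes 0
  expect_false(mixed$strict_significant)  # but the max crosses it
  # ranks run most negative -> most positive final coefficient
  expect_identical(imp$feature_name[order(imp$rank)],
                   imp$feature_name[order(imp$final_coef, imp$feature_name)])
})

test_that("the full pipeline writes a complete, task-configurable bundle", {
  out <- withr::local_tempdir()
  config <- list(scenario = "toy", n_runs = 3, folds = 4, seed = 5,
                 kinds = c("linear", "h"))
  res <- suppressWarnings(run_full_analysis(config, out))
  for (f in c("summary.json", "errors_POA_linear.json", "errors_EFF_h.json",
              "importance_POA_linear.tsv", "coefficients_EFF_linear.tsv",
              "comparisons_POA.tsv", "predicted_POA_h.csv",
              "predicted_EFF_linear.csv"))
    expect_true(file.exists(file.path(out, f)), info = f)
  smry <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(smry$n_pairs, 30)

  out2 <- withr::local_tempdir()
  suppressWarnings(run_full_analysis(
    list(scenario = "toy", n_runs = 3, folds = 4, seed = 5,
         kinds = c("linear", "h"), tasks = "POA"), out2))
  expect_false(any(grepl("EFF", list.files(out2))))
  expect_true(file.exists(file.path(out2, "errors_POA_linear.json")))
})

test_that("file-based inputs run through the pipeline end to end", {
  src <- withr::local_tempdir()
  paths <- make_fixture("toy", src, seed = 2)
  out <- withr::local_tempdir()
  res <- suppressWarnings(run_full_analysis(
    list(host_profiles = paths[["host"]], phage_profiles = paths[["phage"]],
         eop_matrix = paths[["eop"]], n_runs = 2, folds = 4, seed = 9,
         kinds = "linear", tasks = "POA"), out))
  expect_true(file.exists(file.path(out, "errors_POA_linear.json")))
})
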