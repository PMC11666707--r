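#!/usr/bin/env Rscript
# Integration check against the deposited experimental data (not part of
# the desk-scale test suite: it needs the archive downloaded locally).
#
# Download the deposit (doi 10.5281/zenodo.13838668), export the host and
# phage mutation-profile tables as TSV and the cross-infection matrix as
# CSV in the layouts read_mutation_profiles() / read_cross_infection()
# expect, then run:
#
#   Rscript scripts/integration_deposited.R <data_dir> [n_runs]
#
# where <data_dir> contains host_profiles.tsv, phage_profiles.tsv and
# eop_matrix.csv.  Checks the dataset's documented shape (51 x 45 grid,
# 913 positive / 1382 zero cells, 18 host and 176 phage mutations before
# ancestor augmentation) and then runs the full bootstrap protocol
# (default 200 runs; pass a smaller n_runs for a quick look).  Expected
# ballpark at 200 runs: mean POA classification accuracy around 86% for
# the linear model and roughly 40% reduction in EFF validation MAE
# relative to the mean-null model.

suppressMessages(library(phinet))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: integration_deposited.R <data_dir> [n_runs]")
dir <- args[1]
n_runs <- if (length(args) >= 2) as.integer(args[2]) else 200L

host <- read_mutation_profiles(file.path(dir, "host_profiles.tsv"), "host")
phage <- read_mutation_profiles(file.path(dir, "phage_profiles.tsv"), "phage")
eop <- read_cross_infection(file.path(dir, "eop_matrix.csv"))

check <- function(lab, got, want) {
  status <- if (identical(got, want)) "ok" else "MISMATCH"
  cat(sprintf("%-40s got %s, expected %s  [%s]\n", lab, got, want, status))
}
check("host mutations (pre-augmentation)", ncol(host$incidence), 18L)
check("phage mutations (pre-augmentation)", ncol(phage$incidence), 176L)
check("grid cells", length(eop$eop), 2295L)
check("positive (EOP > 0) cells", sum(eop$eop > 0), 913L)
check("zero cells", sum(eop$eop == 0), 1382L)

host <- augment_ancestor(host, rownames(host$incidence)[1])
phage <- augment_ancestor(phage, rownames(phage$incidence)[1])

poa <- binarize(eop)
tab <- log_transform_positive(eop)
bl <- run_bootstrap(host, phage, poa, "linear", "POA",
                    n_runs = n_runs, master_seed = 1)
cat(sprintf("POA linear: mean validation accuracy %.1f%% (null %.1f%%)\n",
            100 * (1 - mean(bl$val_error)),
            100 * (1 - mean(bl$null_val_error))))
be <- run_bootstrap(host, phage, tab, "linear", "EFF",
                    n_runs = n_runs, master_seed = 1)
cat(sprintf("EFF linear: mean validation MAE %.3f (null %.3f, %.0f%% reduction)\n",
            mean(be$val_error), mean(be$null_val_error),
            100 * (1 - mean(be$val_error) / mean(be$null_val_error))))
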