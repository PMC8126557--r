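#!/usr/bin/env Rscript

# Threshold pre-selection of amplifier constructors.
#
# Fits the max(tau)/lambda2 box classifier on each census slice: predict
# "constructor" when the maximal remeeting time is at least the smallest
# value seen among true constructors and the spectral gap is at most the
# largest.  Recall is 100% by construction; precision measures how many
# candidates a fixation-level verification would still have to reject.

suppressPackageStartupMessages(library(transamp))

census_dir <- "results/census"
out_dir <- "results/classifier"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

slices <- list(c(12, 3), c(14, 3), c(16, 3), c(11, 4), c(12, 4), c(13, 4))
rows <- list()
for (spec in slices) {
  N <- spec[1]; k <- spec[2]
  path <- file.path(census_dir, sprintf("census_N%d_k%d.csv", N, k))
  cen <- if (file.exists(path)) read.csv(path) else run_census(N, k)
  if (!any(cen$is_constructor)) next
  rep <- fit_and_score(cen)
  rows[[length(rows) + 1L]] <- data.frame(
    N = N, k = k, tau_threshold = rep$tau_threshold,
    lambda_threshold = rep$lambda_threshold,
    tp = rep$tp, fp = rep$fp, tn = rep$tn, fn = rep$fn,
    pre_percent = round(rep$pre, 4), acc_percent = round(rep$acc, 4))
  message(sprintf(
    "(N = %2d, k = %d): TP %3d FP %4d  PRE = %8.4f%%  ACC = %.4f%%",
    N, k, rep$tp, rep$fp, rep$pre, rep$acc))
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out_dir, "classifier_reports.csv"),
          row.names = FALSE)
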