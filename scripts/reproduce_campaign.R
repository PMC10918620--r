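#!/usr/bin/env Rscript
# Reproduce the full multi-sample uncertainty report from a locally supplied
# measurement campaign (the deposited raw acquisition tables are not shipped
# with this package).
#
# Usage:
#   Rscript scripts/reproduce_campaign.R --data-dir DIR [--ref DIR/refs.tsv]
#          [--runs N] [--seed S] [--out report.kv] [--table-out report.tsv]
#
# DIR must contain one or more run tables (*.tsv or *.csv, the format read
# by read_run_table): per acquisition, label, role, mean_ratio, std_error,
# n_cycles, in sequence order. All runs are reduced to bracketed deltas,
# concatenated, grouped by sample label, and summarized by build_report with
# the classical and Monte Carlo expanded uncertainties. An optional
# reference table supplies literature delta values; labels without one use
# the mean-substitution policy.

suppressPackageStartupMessages(library(ssbmc))

args <- commandArgs(trailingOnly = TRUE)
flag <- function(key, default = NULL) {
  i <- match(paste0("--", key), args)
  if (is.na(i)) default else args[[i + 1L]]
}

data_dir <- flag("data-dir")
if (is.null(data_dir) || !dir.exists(data_dir)) {
  message("reproduce_campaign: supply --data-dir pointing at the deposited ",
          "run tables (not distributed with this package)")
  quit(save = "no", status = 1L)
}

ref_path <- flag("ref")
runs <- as.numeric(flag("runs", "1e6"))
seed <- as.integer(flag("seed", "1"))

files <- list.files(data_dir, pattern = "\\.(tsv|csv)$", full.names = TRUE)
files <- files[!grepl("refs?\\.", basename(files))]
if (length(files) == 0L) {
  message("reproduce_campaign: no run tables found under ", data_dir)
  quit(save = "no", status = 1L)
}

message(sprintf("reproduce_campaign: %d run table(s), runs=%g, seed=%d",
                length(files), runs, seed))
deltas <- do.call(rbind, lapply(files, function(f) ssb_deltas(read_run_table(f))))
reference <- if (!is.null(ref_path)) read_reference_table(ref_path) else NULL

report <- build_report(deltas, reference = reference, runs = runs, seed = seed)
print(report)
out <- flag("out")
if (!is.null(out)) write_report(report, out, format = "keyvalue")
table_out <- flag("table-out")
if (!is.null(table_out)) write_report(report, table_out, format = "table")
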