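#!/usr/bin/env Rscript
# Step 2: the four-policy cost-effectiveness comparison. Evaluates the
# current programme (screening ages 50-69) and the three extensions
# (younger 46-69, older 50-74, both 46-74) on the synthetic baseline from
# step 1 and writes the comparison table: expected costs EC_h, expected
# life-years ET_h, EC/ET, incremental cost, ICER (euros per life-year
# gained, alternative minus reference) and expected breast cancer deaths.

suppressPackageStartupMessages(library(flexscreen))

in_dir <- file.path("scratch", "synthetic_inputs")
if (!dir.exists(in_dir)) stop("run analysis/01_generate_inputs.R first")
baseline <- read_inputs(in_dir)

dir.create("results", showWarnings = FALSE)
tab <- run_table4(baseline, out_csv = file.path("results",
                                                "policy_comparison.csv"))
write_manifest(file.path("results", "policy_comparison_manifest.json"),
               baseline)

cat("Four-policy comparison (synthetic inputs):\n\n")
print(transform(tab, EC = round(EC), ET = round(ET, 1),
                ratio = round(ratio, 2),
                incremental_cost = round(incremental_cost),
                icer = round(icer), bc_deaths = round(bc_deaths, 1)),
      row.names = FALSE)

cat("\nReading: on this synthetic parameter set the screened incidence",
    "\nexceeds the unscreened rate enough that every extension adds",
    "\ndiagnoses and costs without gaining life-years (negative ICERs),",
    "\nthe same behaviour the +10% incidence sensitivity produces on the",
    "\nregistry-based inputs. The synthetic generator makes no attempt to",
    "\nreproduce the Finnish rates themselves.\n")
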