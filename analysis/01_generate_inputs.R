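#!/usr/bin/env Rscript
# Step 1: build the synthetic Finnish-like parameter set the rest of the
# workflow consumes. Everything here is generated data emulating the
# *structure* of the registry inputs (age-increasing incidence with a
# first-screen peak and post-screening deficit, screening-favourable stage
# distributions, excess mortality decaying to background within 18 years);
# only the treatment-cost tables and the 30 EUR screening cost are the
# published constants. Parameter files are written in the package's CSV
# layout so the downstream steps exercise the full load/validate path.

suppressPackageStartupMessages(library(flexscreen))

cfg <- generator_config(seed = 2026L, J = 27L)
inputs <- generate_inputs(cfg)

out_dir <- file.path("scratch", "synthetic_inputs")
write_inputs(inputs, out_dir)

stopifnot(length(validate_inputs(read_inputs(out_dir))) == 0L)

cat("Synthetic baseline written to", out_dir, "\n")
cat(sprintf("  %d age groups (ages %d-%d), N0 = %g invitees\n",
            inputs$grid$J, lower_age(inputs$grid, 1),
            lower_age(inputs$grid, inputs$grid$J) + 1L, inputs$N0))
cat(sprintf("  incidence at 46-47 (NS): %.4f; at 68-69 (S): %.4f\n",
            inputs$incidence[1, "NS"], inputs$incidence[12, "S"]))
cat(sprintf("  localized+in situ share | screened: %.2f, unscreened: %.2f\n",
            mean(inputs$stages[, "S", "k1"] + inputs$stages[, "S", "k4"]),
            mean(inputs$stages[, "NS", "k1"] + inputs$stages[, "NS", "k4"])))
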