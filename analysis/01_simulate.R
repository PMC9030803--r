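#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study cohort.
#
# Generates the default 85-protein cohort (lengths 50-500, uniform residue
# usage) with per-residue structural profiles and activities planted on
# three features spanning the descriptor families (a dipeptide, a CTD
# distribution value, and a solvent-accessibility summary), then writes
# the cohort to disk in the package's exchange formats so the later
# stages exercise the full I/O path.

suppressPackageStartupMessages(library(splicefactoR))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- simulation_spec(rng_seed = 1)
d <- simulate_dataset(spec)

write_protein_fasta(d$proteins, file.path(out, "cohort.fasta"))
write_activities(d$proteins, file.path(out, "activities.tsv"))
write_profiles(d$profiles, file.path(out, "profiles"))
write_report(d$truth, file.path(out, "ground_truth.json"))

message(sprintf("cohort: %d proteins, lengths %d-%d",
                nrow(d$proteins), min(nchar(d$proteins$sequence)),
                max(nchar(d$proteins$sequence))))
message(sprintf("activity range: [%.2f, %.2f], planted on: %s",
                min(d$proteins$activity), max(d$proteins$activity),
                paste(d$truth$planted_features, collapse = ", ")))
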