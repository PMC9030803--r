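#!/usr/bin/env Rscript
# Stage 2 — encode the cohort into the 700-feature matrix.
#
# Reads the cohort written by stage 1 through the standard readers,
# assembles the full encoding (AAC 20 + Dual-AAC 400 + CTD 84 + SS3/SS8
# 172 + track summaries 24 = 700), removes near-zero and constant
# columns, and z-scores the survivors.  The filtered count depends on
# which dipeptides/states happen to be absent from the cohort.

suppressPackageStartupMessages(library(splicefactoR))

data_dir <- "results/data"
proteins <- read_proteins(file.path(data_dir, "cohort.fasta"),
                          file.path(data_dir, "activities.tsv"))
profiles <- read_profiles(file.path(data_dir, "profiles"),
                          ids = proteins$id)

fm <- assemble_features(proteins, profiles)
fm_filt <- drop_near_zero(fm, epsilon = 1e-8)
fm_norm <- zscore_features(fm_filt)

write_feature_matrix(fm_norm, file.path("results", "features_zscored.tsv"))
write_report(list(n_proteins = nrow(proteins),
                  n_features_raw = ncol(as.matrix(fm)),
                  n_features_filtered = ncol(as.matrix(fm_norm)),
                  dropped = fm_filt$dropped),
             file.path("results", "feature_counts.json"))

message(sprintf("feature matrix: %d x %d raw -> %d after filtering",
                nrow(as.matrix(fm)), ncol(as.matrix(fm)),
                ncol(as.matrix(fm_norm))))
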