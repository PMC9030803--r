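#!/usr/bin/env Rscript
# Stage 4 — model evaluation: PLSR component sweep, cross-validated
# performance of the full matrix and of the best forward subset, the
# per-family importance decomposition, and reduced-grid RFR/SVMR
# baselines.

suppressPackageStartupMessages(library(splicefactoR))

proteins <- read_proteins("results/data/cohort.fasta",
                          "results/data/activities.tsv")
fm <- read_feature_matrix("results/features_zscored.tsv",
                          normalized = TRUE)
y <- proteins$activity
x <- as.matrix(fm)
folds <- make_cv_folds(nrow(x), 5, seed = 1)

# component sweep 1..10 on the full filtered matrix
sw <- sweep_components(fm, y, components = 1:10, fold_assign = folds)
utils::write.table(sw$sweep, "results/component_sweep.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("component sweep: best at %d components",
                sw$best_n_components))

# full matrix vs best forward subset
fw <- read_report("results/forward_search.json")
best_k <- 2 + which.max(fw$trace$score)
best_set <- fw$selected[seq_len(best_k)]
cv_full <- cross_validate(fm, y, n_components = 3, fold_assign = folds)
cv_best <- cross_validate(x[, best_set, drop = FALSE], y,
                          n_components = 3, fold_assign = folds)
write_report(list(full_matrix = cv_full, best_subset = cv_best,
                  best_subset_features = best_set),
             "results/model_evaluation.json")
message(sprintf(
  "CV Spearman: full matrix %.3f, best %d-feature subset %.3f",
  cv_full$mean["spearman_gamma"], length(best_set),
  cv_best$mean["spearman_gamma"]))

# family decomposition of the best subset
groups <- split(best_set, feature_family(best_set))
groups <- groups[lengths(groups) > 0]
imp <- subset_importance(fm, y, groups, n_components = 3,
                         fold_assign = folds)
utils::write.table(imp, "results/subset_importance.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("family Spearman: ",
        paste(sprintf("%s %.3f", imp$family, imp$spearman_gamma),
              collapse = ", "))

# baselines on the best subset with reduced grids (the full grids are
# the package defaults; see baseline_grids())
bl <- fit_baselines(
  x[, best_set, drop = FALSE], y,
  grids = baseline_grids(rf_trees = c(10, 25, 50, 99),
                         rf_mtry = c(2, 5, 10),
                         svm_cost = c(0.1, 1, 10),
                         svm_gamma = 2^seq(-6, 2, by = 2)),
  fold_assign = folds, seed = 1)
write_report(list(rfr_best = as.list(bl$rfr$best),
                  svmr_best = as.list(bl$svmr$best)),
             "results/baselines.json")
message(sprintf("baselines (best subset): RFR %.3f, SVMR %.3f vs PLSR %.3f",
                bl$rfr$best$spearman, bl$svmr$best$spearman,
                cv_best$mean["spearman_gamma"]))
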