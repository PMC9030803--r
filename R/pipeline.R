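# End-to-end orchestration: featurize -> filter/normalize -> mRMR ->
# forward search -> component sweep -> per-family importance.

#' Validated run configuration
#'
#' Collects the tunable parameters of the pipeline with their defaults:
#' 3 PLSR components, 5-fold cross-validation, near-zero threshold 1e-8,
#' 3-state discretization at mean +- 0.5 sd, difference-scheme mRMR, the
#' explained-variance R2 form, and a 2-feature initial forward subset.
#'
#' @param pls_n_components PLSR components (>= 1).
#' @param cv_folds Cross-validation folds (>= 2).
#' @param rng_seed Integer seed for fold draws.
#' @param near_zero_epsilon Near-zero feature threshold.
#' @param mi_bins_sigma Discretization band half-width (sd units).
#' @param mrmr_scheme `"difference"` or `"quotient"`.
#' @param r2_form `"as_printed"` or `"one_minus_sse_over_sst"`.
#' @param forward_initial_k Initial forward-search subset size.
#' @param max_forward_features Forward-search stopping size.
#' @param forward_pool_size Candidate pool size (head of the mRMR list);
#'   `NULL` for all features.
#' @return A validated `run_config` list.
#' @export
run_config <- function(pls_n_components = 3, cv_folds = 5, rng_seed = 1,
                       near_zero_epsilon = 1e-8, mi_bins_sigma = 0.5,
                       mrmr_scheme = "difference",
                       r2_form = "as_printed", forward_initial_k = 2,
                       max_forward_features = 30,
                       forward_pool_size = 100) {
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  if (pls_n_components < 1) stop("pls_n_components must be >= 1")
  mrmr_scheme <- match.arg(mrmr_scheme, c("difference", "quotient"))
  r2_form <- match.arg(r2_form,
                       c("as_printed", "one_minus_sse_over_sst"))
  structure(list(pls_n_components = pls_n_components,
                 cv_folds = cv_folds, rng_seed = as.integer(rng_seed),
                 near_zero_epsilon = near_zero_epsilon,
                 mi_bins_sigma = mi_bins_sigma,
                 mrmr_scheme = mrmr_scheme, r2_form = r2_form,
                 forward_initial_k = forward_initial_k,
                 max_forward_features = max_forward_features,
                 forward_pool_size = forward_pool_size),
            class = "run_config")
}

#' Run the full activity-prediction pipeline
#'
#' Executes the analysis stages in order on a labelled cohort: feature
#' assembly (700 columns), near-zero filtering, z-scoring, mRMR ranking,
#' forward feature search, PLSR component sweep on the full filtered
#' matrix, and the per-family importance decomposition of the selected
#' subset.  Deterministic under (`cohort`, `config`).
#'
#' @param proteins Labelled cohort data.frame (`id`, `sequence`,
#'   `activity` with no NA).
#' @param profiles Matching structural profiles.
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, JSON/TSV reports and a
#'   manifest are written there.
#' @return List with `features` (normalized `feature_matrix`), `mrmr`,
#'   `forward` (`selection_state`), `sweep`, `importance`, `full_model_cv`
#'   and `manifest`.
#' @export
run_activity_pipeline <- function(proteins, profiles,
                                  config = run_config(),
                                  out_dir = NULL) {
  if (anyNA(proteins$activity)) {
    stop("all proteins must have an activity label")
  }
  y <- proteins$activity
  fm <- assemble_features(proteins, profiles)
  fm_filt <- drop_near_zero(fm, epsilon = config$near_zero_epsilon)
  fm_norm <- zscore_features(fm_filt)
  mrmr <- rank_mrmr(fm_norm, y, scheme = config$mrmr_scheme,
                    sigma_mult = config$mi_bins_sigma)
  fwd <- forward_search(fm_norm, y, mrmr$mrmr_order,
                        k_init = config$forward_initial_k,
                        n_components = config$pls_n_components,
                        max_features = config$max_forward_features,
                        folds = config$cv_folds, seed = config$rng_seed,
                        pool_size = config$forward_pool_size)
  full_cv <- cross_validate(fm_norm, y,
                            n_components = config$pls_n_components,
                            folds = config$cv_folds,
                            seed = config$rng_seed,
                            r2_form = config$r2_form)
  sweep <- sweep_components(fm_norm, y, components = 1:10,
                            folds = config$cv_folds,
                            seed = config$rng_seed)
  best_k <- if (nrow(fwd$trace) > 0) {
    config$forward_initial_k + which.max(fwd$trace$score)
  } else {
    length(fwd$selected)
  }
  best_set <- fwd$selected[seq_len(best_k)]
  fam <- feature_family(best_set)
  groups <- split(best_set, fam)
  groups <- groups[lengths(groups) > 0]
  importance <- subset_importance(fm_norm, y, groups,
                                  n_components = config$pls_n_components,
                                  folds = config$cv_folds,
                                  seed = config$rng_seed)
  manifest <- list(
    n_proteins = nrow(proteins),
    n_features_raw = ncol(fm$x),
    n_features_filtered = ncol(fm_norm$x),
    config = unclass(config),
    stages = c("featurize", "filter", "normalize", "mrmr",
               "forward_search", "component_sweep", "importance"),
    best_forward_subset = best_set,
    best_forward_spearman = if (nrow(fwd$trace) > 0) {
      max(fwd$trace$score)
    } else NA_real_,
    best_n_components = sweep$best_n_components)
  result <- list(features = fm_norm, mrmr = mrmr, forward = fwd,
                 sweep = sweep, importance = importance,
                 full_model_cv = full_cv, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(manifest, file.path(out_dir, "manifest.json"))
    write_report(list(maxrel_order = mrmr$maxrel_order,
                      mrmr_order = mrmr$mrmr_order,
                      relevance = as.list(mrmr$relevance)),
                 file.path(out_dir, "mrmr.json"))
    write_report(list(selected = fwd$selected, initial = fwd$initial,
                      trace = fwd$trace),
                 file.path(out_dir, "forward_search.json"))
    write_report(full_cv, file.path(out_dir, "full_model_cv.json"))
    utils::write.table(sweep$sweep,
                       file.path(out_dir, "component_sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(importance,
                       file.path(out_dir, "subset_importance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  result
}
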