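#' Classify one simulated fast-spiking cohort
#'
#' End-to-end classification run: simulate the mixed FS cohort, extract
#' the eight intrinsic features, z-standardize, Ward-cluster, cut at k = 2
#' and count misclassification against the generator's ground truth --
#' once with all eight features and once with only the subthreshold trio
#' (input resistance, time constant, sag).
#'
#' @param seed integer seed for the cohort.
#' @param ... passed to [simulate_fs_cohort()].
#' @return list with `features` (the per-cell table),
#'   `mis_8feat` (misclassified cells of 25, eight features),
#'   `mis_3feat_sst` (misclassified SST-like cells, subthreshold trio) and
#'   `mis_3feat` (all misclassified cells, subthreshold trio).
#' @export
classify_fs_cohort <- function(seed, ...) {
  cells <- simulate_fs_cohort(seed = seed, ...)
  feats <- extract_features_table(cells)
  run_cut <- function(cols) {
    m <- as.matrix(feats[, cols])
    rownames(m) <- feats$cell_id
    asg <- cluster_cut(ward_linkage(standardize(m)), k = 2)
    misclassification(asg$labels, feats$class)
  }
  mis8 <- run_cut(feature_names())
  mis3 <- run_cut(subthreshold_features())
  sst_idx <- which(feats$class == "SST")
  list(features = feats,
       mis_8feat = mis8$count,
       mis_3feat = mis3$count,
       mis_3feat_sst = length(intersect(mis3$misclassified, sst_idx)))
}

#' Misclassification medians over repeated cohorts
#'
#' Repeats [classify_fs_cohort()] over `n_seeds` seeds derived from a
#' master seed and reports the medians of the misclassification counts.
#'
#' @param master_seed integer master seed.
#' @param n_seeds number of replicate cohorts (default 100).
#' @param ... passed to [classify_fs_cohort()].
#' @return list with `median_mis_8feat`, `median_mis_3feat_sst` and the
#'   per-seed `runs` data frame.
#' @export
fs_misclassification_study <- function(master_seed = 1, n_seeds = 100, ...) {
  seeds <- master_seed * 10000 + seq_len(n_seeds)
  runs <- do.call(rbind, lapply(seeds, function(s) {
    r <- classify_fs_cohort(s, ...)
    data.frame(seed = s, mis_8feat = r$mis_8feat, mis_3feat = r$mis_3feat,
               mis_3feat_sst = r$mis_3feat_sst)
  }))
  list(median_mis_8feat = stats::median(runs$mis_8feat),
       median_mis_3feat_sst = stats::median(runs$mis_3feat_sst),
       runs = runs)
}

#' Population feature means for a preset
#'
#' Simulates `n` cells of a preset and returns the mean of each extracted
#' feature, the calibration-recovery quantity of the generator contract.
#'
#' @param preset_name preset, or vector of presets passed through.
#' @param n population size.
#' @param seed integer seed.
#' @return named numeric vector of feature means (invalid features are
#'   dropped per cell).
#' @export
preset_feature_means <- function(preset_name, n = 50, seed = 1) {
  cells <- simulate_population(preset_name, n, seed = seed)
  feats <- extract_features_table(cells)
  vapply(feature_names(), function(f) mean(feats[[f]], na.rm = TRUE),
         numeric(1))
}
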