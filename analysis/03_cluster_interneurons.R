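#!/usr/bin/env Rscript
## Classification workflow over the extracted features:
##  1. sequential Ward clustering of the full cohort (all 8 features,
##     then dropping G42-like cells, then dropping RS-like cells),
##  2. the two-cluster FS comparison (8 features vs subthreshold trio),
##  3. misclassification medians over 100 replicate cohorts.

suppressMessages(library(apcephys))

features <- read_features_tsv("results/features.tsv")
features$group <- features$class

plan <- list(
  list(features = feature_names(), exclude_groups = character(0), k = 4),
  list(features = feature_names(), exclude_groups = c("G42", "G42-Neo"),
       k = 3),
  list(features = feature_names(), exclude_groups = c("GIN", "RS"), k = 2))
# RS-like SST cells are excluded with the GIN group at the last stage, as in
# the staged workflow; label them by phenotype first
features$group[features$phenotype == "RS" & features$class == "SST"] <- "RS"

stages <- sequential_cluster(features, plan)
for (i in seq_along(stages)) {
  st <- stages[[i]]
  tab <- table(cluster = st$assignment$labels,
               class = features$group[st$kept])
  message(sprintf("stage %d (k=%d, %d cells):", i, st$assignment$k,
                  length(st$kept)))
  print(tab)
  export_newick(st$tree, sprintf("results/dendrogram_stage%d.nwk", i))
  write.table(data.frame(cell_id = names(st$assignment$labels),
                         cluster = st$assignment$labels),
              sprintf("results/assignments_stage%d.tsv", i), sep = "\t",
              row.names = FALSE, quote = FALSE)
}

fs <- features[features$phenotype %in% c("FS-tonic", "FS-stutter") &
                 features$class %in% c("SST", "PV"), ]
for (cols in list(all8 = feature_names(), trio = subthreshold_features())) {
  m <- as.matrix(fs[, cols]); rownames(m) <- fs$cell_id
  asg <- cluster_cut(ward_linkage(standardize(m)), 2)
  mis <- misclassification(asg$labels, fs$class)
  message(sprintf("FS cohort, %d features: %d of %d misclassified",
                  length(cols), mis$count, nrow(fs)))
}

study <- fs_misclassification_study(master_seed = 7, n_seeds = 100)
message(sprintf(paste0("over 100 replicate cohorts: median %g of 25 ",
                       "misclassified (8 features); median %g SST cells ",
                       "misclassified (subthreshold trio)"),
                study$median_mis_8feat, study$median_mis_3feat_sst))
write.table(study$runs, "results/misclassification_runs.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
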