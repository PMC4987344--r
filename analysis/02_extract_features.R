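#!/usr/bin/env Rscript
## Extract the eight intrinsic properties from the simulated sweep tables
## and summarise them per preset (a Table-1-style summary: mean +/- SE).

suppressMessages(library(apcephys))

out <- "results/simulated"
manifest <- read.table(file.path(out, "manifest.tsv"), sep = "\t",
                       header = TRUE)

features <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
  id <- manifest$cell_id[i]
  sub <- read_sweep_set(file.path(out, "sweeps", paste0(id, "_sub.csv")))
  sup <- read_sweep_set(file.path(out, "sweeps", paste0(id, "_supra.csv")))
  cbind(manifest[i, c("preset", "class", "phenotype")],
        extract_features(sub, sup))
}))
write_features_tsv(features, "results/features.tsv")

fmt <- function(x) sprintf("%.3g ± %.2g", mean(x, na.rm = TRUE),
                           sd(x, na.rm = TRUE) / sqrt(sum(is.finite(x))))
summary_tab <- do.call(rbind, lapply(split(features, features$preset),
  function(d) data.frame(preset = d$preset[1], n = nrow(d),
                         t(vapply(feature_names(),
                                  function(f) fmt(d[[f]]), character(1))))))
write.table(summary_tab, "results/feature_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("per-preset feature summary (mean ± SE):")
print(summary_tab, row.names = FALSE)
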