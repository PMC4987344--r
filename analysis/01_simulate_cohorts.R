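#!/usr/bin/env Rscript
## Simulate the study's synthetic cohorts and write them to disk:
##  - a Table-1-style cohort covering every interneuron preset
##    (current-clamp sweep tables + JSON sidecars + ground-truth manifest),
##  - the six pyramidal-cell gabazine experiments,
##  - ten synthetic anatomy sections per reporter line.
## All randomness flows from one master seed.

suppressMessages(library(apcephys))

master_seed <- 20260924
out <- "results/simulated"
dir.create(file.path(out, "sweeps"), recursive = TRUE, showWarnings = FALSE)

cohort_spec <- c("RS-SST" = 6, "GIN-RS" = 10, "FS-SST-tonic" = 11,
                 "FS-SST-stutter" = 3, "FS-PV-stutter" = 8,
                 "FS-PV-tonic" = 3, "G42-APC" = 17, "G42-Neo" = 4)
presets <- rep(names(cohort_spec), cohort_spec)
cells <- simulate_population(presets, length(presets), seed = master_seed)

manifest <- do.call(rbind, lapply(cells, function(cell) {
  for (proto in c("sub", "supra")) {
    path <- file.path(out, "sweeps",
                      sprintf("%s_%s.csv", cell$record$cell_id, proto))
    write_sweep_set(cell[[proto]], path,
                    extra = list(master_seed = master_seed,
                                 protocol_kind = proto))
  }
  data.frame(cell_id = cell$record$cell_id, preset = cell$record$preset,
             class = cell$record$class, phenotype = cell$record$phenotype)
}))
write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("simulated %d cells across %d presets -> %s",
                nrow(manifest), length(cohort_spec), out))

saveRDS(simulate_pc_cohort(n = 6, seed = master_seed + 1),
        file.path(out, "pc_gabazine_cohort.rds"))
message("simulated 6 pyramidal-cell gabazine experiments")

for (line in c("SST-line", "PV-line")) {
  preset <- marker_preset(line)
  set.seed(master_seed + match(line, c("SST-line", "PV-line")))
  sections <- do.call(rbind, lapply(1:10, function(i)
    cbind(section = i, pattern_counts(
      generate_point_pattern(preset$section_area, preset$density,
                             preset$colabel_probs)))))
  write.table(sections,
              file.path(out, sprintf("sections_%s.tsv", line)),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
message("simulated anatomy sections for both reporter lines")
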