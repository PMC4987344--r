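#!/usr/bin/env Rscript
## Quantify the simulated light-evoked IPSC experiments: trial averages,
## charges, the 10 pA inclusion filter, and the somatic/distal/other
## decomposition of pyramidal-cell inhibition.

suppressMessages(library(apcephys))

cohort <- readRDS("results/simulated/pc_gabazine_cohort.rds")

rows <- do.call(rbind, lapply(seq_along(cohort), function(i) {
  res <- measure_ipsc_experiment(cohort[[i]])
  kept <- include_filter(res$measurements["baseline"])
  d <- res$decomposition
  data.frame(cell = i,
             q_baseline = res$charges[["baseline"]],
             q_gz_soma = res$charges[["GZ-soma"]],
             q_gz_both = res$charges[["GZ-both"]],
             included = length(kept) == 1,
             somatic_percent = d$somatic_percent,
             distal_percent = d$distal_percent,
             other_percent = d$other_percent)
}))
write.table(rows, "results/ipsc_decomposition.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

message(sprintf("baseline charge: %.1f ± %.2f pA*s (mean ± SE, n = %d)",
                mean(rows$q_baseline),
                sd(rows$q_baseline) / sqrt(nrow(rows)), nrow(rows)))
message(sprintf("somatic GZ: %.1f pA*s; both sites: %.1f pA*s",
                mean(rows$q_gz_soma), mean(rows$q_gz_both)))
message(sprintf(paste0("decomposition (per-cell means): somatic %.1f%%, ",
                       "distal %.1f%%, other %.1f%%"),
                mean(rows$somatic_percent), mean(rows$distal_percent),
                mean(rows$other_percent)))

# paired somatic-block effect across the six cells (small n -> WSR)
res <- run_test("WSR", list(x = rows$q_baseline, y = rows$q_gz_soma))
message(sprintf("baseline vs somatic GZ, WSR: p = %.4g", res$p_value))
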