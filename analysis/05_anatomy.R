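#!/usr/bin/env Rscript
## Laminar-density, co-labelling and layer fluorescence-ratio statistics on
## the synthetic anatomy sections.

suppressMessages(library(apcephys))

out <- "results/simulated"
for (line in c("SST-line", "PV-line")) {
  sec <- read.table(file.path(out, sprintf("sections_%s.tsv", line)),
                    sep = "\t", header = TRUE)
  dens <- density_per_mm2(sec$reporter, sec$area_mm2)
  marker <- setdiff(names(sec), c("section", "area_mm2", "reporter",
                                  grep("^reporter_", names(sec), value = TRUE)))
  pct <- mapply(colabel_percent, sec[[paste0("reporter_", marker)]],
                sec$reporter)
  message(sprintf(paste0("%s: density %.1f ± %.2f cells/mm^2; ",
                         "%s co-labelling %.1f ± %.2f%% (n = %d sections)"),
                  line, mean(dens), sd(dens) / sqrt(length(dens)), marker,
                  mean(pct), sd(pct) / sqrt(length(pct)), nrow(sec)))
}

# layer fluorescence ratio: SST-line sections have bright L1B neuropil
set.seed(99)
ratio <- function(l1b_mean) replicate(7, {
  p <- generate_image_patch(40, l1b_mean, noise_sd = 4)
  intensity_ratio(p$l1b, p$l1a)
})
r_sst <- ratio(70); r_pv <- ratio(25)
d <- comparison_design(c(r_sst, r_pv), rep(c("SST", "PV"), each = 7))
test <- run_test(select_test(d),
                 list(x = r_sst, y = r_pv))
message(sprintf(paste0("L1B:L1A ratio %.2f (SST-line) vs %.2f (PV-line), ",
                       "%s p = %.4g"),
                mean(r_sst), mean(r_pv), test$test, test$p_value))
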