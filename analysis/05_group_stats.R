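#!/usr/bin/env Rscript
# Replicate-level statistics: Student's t-tests (alpha = 0.05) comparing
# conditions, mirroring how the permeability deltas and zigzag indices are
# compared across osmotic conditions and genotypes.

library(paraperm)

deltas <- read.csv("results/delta_115min.csv")
zig <- read.csv("results/zigzag_indices.csv")

comparisons <- list(
  list(label = "delta P_Na: wt_hypo vs wt_iso",
       a = deltas$delta_p_na[deltas$condition == "wt_hypo"],
       b = deltas$delta_p_na[deltas$condition == "wt_iso"]),
  list(label = "beta(120): wt_hypo vs wt_iso",
       a = deltas$beta_120min[deltas$condition == "wt_hypo"],
       b = deltas$beta_120min[deltas$condition == "wt_iso"]),
  list(label = "beta(120): rescue vs ko",
       a = deltas$beta_120min[deltas$condition == "rescue"],
       b = deltas$beta_120min[deltas$condition == "ko"]),
  list(label = "zigzag: wt_hypo vs wt_iso",
       a = zig$index[zig$condition == "wt_hypo"],
       b = zig$index[zig$condition == "wt_iso"]),
  list(label = "zigzag: ko_hypo vs ko_iso",
       a = zig$index[zig$condition == "ko_hypo"],
       b = zig$index[zig$condition == "ko_iso"])
)

tab <- do.call(rbind, lapply(comparisons, function(cmp) {
  res <- compare_groups(cmp$a, cmp$b)
  data.frame(comparison = cmp$label,
             mean_a = mean(cmp$a), mean_b = mean(cmp$b),
             t = res$t, p = res$p, significant = res$significant)
}))
write.csv(tab, "results/group_tests.csv", row.names = FALSE)

cat("Student's t-tests (pooled variance, two-sided, alpha = 0.05):\n")
for (i in seq_len(nrow(tab)))
  cat(sprintf("  %-32s t = %7.2f  p = %8.2e  %s\n",
              tab$comparison[i], tab$t[i], tab$p[i],
              if (tab$significant[i]) "*" else "n.s."))
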