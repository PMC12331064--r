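#!/usr/bin/env Rscript
# Stage 6: group statistics on the stage-5 improvements — paired t contrasts
# (full vs baseline model; mixed vs baseline-only condition) and
# within-subject standard errors for repeated-measures error bars.

library(wordtrf)

imp <- read.csv("results/encoding_improvements.csv")
i0 <- imp[imp$condition == "baseline_only", ]
i1 <- imp[imp$condition == "rnn_mixed", ]

t_full_vs_base <- paired_t(i1$ve_full, i1$ve_base)
t_mixed_vs_null <- paired_t(i1$improvement_pct, i0$improvement_pct)
se <- within_subject_se(cbind(base = i1$ve_base, full = i1$ve_full))

out <- data.frame(
  contrast = c("ve_full_vs_ve_base (mixed)", "improvement_mixed_vs_baseline"),
  t = c(t_full_vs_base$t, t_mixed_vs_null$t),
  df = c(t_full_vs_base$df, t_mixed_vs_null$df),
  p = c(t_full_vs_base$p, t_mixed_vs_null$p))
write.csv(out, "results/group_stats.csv", row.names = FALSE)
write.csv(data.frame(condition = names(se), within_subject_se = se),
          "results/within_subject_se.csv", row.names = FALSE)
message(sprintf("full vs baseline (mixed): t(%d) = %.2f, p = %.2g",
                out$df[1], out$t[1], out$p[1]))
message(sprintf("mixed vs baseline-only improvement: t(%d) = %.2f, p = %.2g",
                out$df[2], out$t[2], out$p[2]))
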