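#!/usr/bin/env Rscript
# Stage 1: build the synthetic lexicon and multi-talker tokens.
#
# 50 words over a 20-phoneme inventory with a 0.6 neighborhood density, so
# onset-sharing cohorts exist at several depths; 4 talkers (1 reference +
# 3 rate/template-shifted voices). Writes the lexicon table and a cohort
# summary under results/.

library(wordtrf)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

lex <- build_lexicon(50, n_talkers = 4, neighborhood_density = 0.6, seed = 3)
tok <- synthesize_tokens(lex, seed = 4)
saveRDS(list(lex = lex, tok = tok), "scratch/lexicon_tokens.rds")

write_lexicon(lex, "results/lexicon.tsv")

# cohort structure: how many words share k onset phonemes with some other word
overlap <- vapply(seq_along(lex$words), function(i)
  max(vapply(setdiff(seq_along(lex$words), i), function(j)
    shared_onset_phonemes(lex$words[[i]], lex$words[[j]]), integer(1))),
  integer(1))
summary_df <- as.data.frame(table(max_shared_onset = overlap))
write.csv(summary_df, "results/cohort_depths.csv", row.names = FALSE)

durs <- unlist(lapply(seq_len(4), function(tk)
  vapply(tok$tokens[[tk]], `[[`, integer(1), "duration_frames")))
message("lexicon: 50 words; cohort depth distribution:")
print(summary_df)
message("token durations (frames at 100 Hz): ",
        paste(range(durs), collapse = "-"),
        ", mean ", round(mean(durs), 1))
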