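#!/usr/bin/env Rscript
# Stage 4: reduce hidden-unit activity to population predictors. For the bce
# model, run a 100 s stimulus stream through the network and build the two
# predictors per unit group (summed |h| magnitude, rectified change in |h|),
# grouped by layer and by K-means over unit time courses (K = 4), resampled
# to the 50 Hz analysis rate. Writes predictor summaries and the stimulus
# stream artifacts for stage 5.

library(wordtrf)

inputs <- readRDS("scratch/lexicon_tokens.rds")
models <- readRDS("scratch/models.rds")
tok <- inputs$tok

stim <- build_training_stream(tok, 10000, seed = 13)
run <- run_model(models$bce, stim)

p_layer <- build_predictor_set(run$hidden, layer_grouping(run$hidden))
p_k4 <- build_predictor_set(run$hidden,
                            kmeans_grouping(run$hidden, 4, seed = 21))

saveRDS(list(stim = stim, p_layer = p_layer, p_k4 = p_k4),
        "scratch/predictors.rds")

summ <- function(ps, label) data.frame(
  grouping = label, predictor = rownames(ps$x),
  mean = rowMeans(ps$x), sd = apply(ps$x, 1, sd))
write.csv(rbind(summ(p_layer, "layer"), summ(p_k4, "kmeans4")),
          "results/linking_predictors.csv", row.names = FALSE)
message("layer grouping: ", nrow(p_layer$x), " predictors; K-means (K=4): ",
        nrow(p_k4$x), " predictors at ", p_layer$rate, " Hz")
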