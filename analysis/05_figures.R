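#!/usr/bin/env Rscript
# Stage 5: figures.
#
# Smooth age effects per margin with 95% bands, estimated county effects,
# and the county map of the joint probability P(lbw=1, ptb=1) for the
# representative profile, smoking and non-smoking.

suppressPackageStartupMessages(library(copbirth))

fit <- readRDS("results/fit.rds")
graph <- read_adjacency("results/county_adjacency.txt")
ce <- read.csv("results/county_effects.csv",
               colClasses = c(county = "character"))
coords <- as.matrix(ce[, c("x", "y")])
rownames(coords) <- ce$county
dir.create("results/figures", showWarnings = FALSE)

png("results/figures/age_smooths.png", width = 1200, height = 550, res = 120)
op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
plot_smooth(fit, "eq1:s(age)", seed = 5, main = "low birth weight")
plot_smooth(fit, "eq2:s(age)", seed = 5, main = "preterm birth")
par(op); dev.off()

# county contributions on the predictor scale
sm1 <- plot_smooth(fit, "eq1:mrf(county)", seed = 5, plot = FALSE)
sm2 <- plot_smooth(fit, "eq2:mrf(county)", seed = 5, plot = FALSE)
png("results/figures/county_effects.png", width = 1200, height = 550,
    res = 120)
op <- par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
plot_map(setNames(sm1$fit, graph$region_ids), graph, coords,
         main = "county effect, lbw predictor")
plot_map(setNames(sm2$fit, graph$region_ids), graph, coords,
         main = "county effect, ptb predictor")
par(op); dev.off()

# joint probability by county for the representative mother
prof_for <- function(cty, smoke) data.frame(
  ethnicity = "White", educ = "Tertiary", firstbirth = 0, marital = 1,
  smoke = smoke, age = 26, county = cty)
j_ns <- sapply(graph$region_ids, function(cc)
  predict_quantity(fit, prof_for(cc, 0), "joint11", n_sim = 10,
                   seed = 6)$estimate)
j_sm <- sapply(graph$region_ids, function(cc)
  predict_quantity(fit, prof_for(cc, 1), "joint11", n_sim = 10,
                   seed = 6)$estimate)
png("results/figures/joint_probability_maps.png", width = 1200, height = 550,
    res = 120)
op <- par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
plot_map(100 * j_ns, graph, coords,
         main = "P(lbw, ptb) %, representative, non-smoker")
plot_map(100 * j_sm, graph, coords,
         main = "P(lbw, ptb) %, representative, smoker")
par(op); dev.off()

write.csv(data.frame(county = graph$region_ids,
                     joint_nonsmoker_pct = 100 * j_ns,
                     joint_smoker_pct = 100 * j_sm),
          "results/joint_probability_by_county.csv", row.names = FALSE)
cat("figures written to results/figures/\n")
cat(sprintf("joint probability range (non-smoker): %.2f%% to %.2f%%\n",
            100 * min(j_ns), 100 * max(j_ns)))
cat(sprintf("joint probability range (smoker):     %.2f%% to %.2f%%\n",
            100 * min(j_sm), 100 * max(j_sm)))
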