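#!/usr/bin/env Rscript
# Stage 1: generate the synthetic birth cohort.
#
# Builds a 10x10 county lattice with spatially smooth GMRF effects, draws a
# 20,000 record cohort from the default truth (published point estimates for
# the parametric effects, flat-then-rising lbw age effect, U-shaped ptb age
# effect, education-dependent latent correlation), and writes the data CSV,
# the adjacency edge list and the truth metadata.

suppressPackageStartupMessages({
  library(copbirth)
  library(jsonlite)
})

seed <- 1
dir.create("results", showWarnings = FALSE)

county <- make_county_graph(10, 10, spatial_sd = 0.15, seed = seed)
truth <- default_truth(n = 20000)
dat <- generate_births(truth, county, seed = seed + 1)

write.csv(dat, "results/synthetic_births.csv", row.names = FALSE)
write_adjacency(county$graph, "results/county_adjacency.txt")
write.csv(data.frame(county = county$graph$region_ids,
                     x = county$coords[, 1], y = county$coords[, 2],
                     spatial_lbw = unname(county$spatial1),
                     spatial_ptb = unname(county$spatial2)),
          "results/county_effects.csv", row.names = FALSE)
write_json(list(seed = seed, n = nrow(dat),
                beta_lbw = as.list(truth$beta1),
                beta_ptb = as.list(truth$beta2),
                beta_theta = as.list(truth$beta_theta),
                spatial_sd = truth$spatial_sd,
                age_mean = truth$age_mean, age_sd = truth$age_sd,
                age_range = truth$age_range,
                covariate_dist = truth$covariate_dist),
           "results/sim_truth.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("cohort: %d records, %d counties\n", nrow(dat),
            length(county$graph$region_ids)))
cat(sprintf("event rates: lbw %.1f%%, ptb %.1f%%, both %.1f%%\n",
            100 * mean(dat$lbw), 100 * mean(dat$ptb),
            100 * mean(dat$lbw & dat$ptb)))
cat(sprintf("age: %.1f%% under 20, %.1f%% aged 35+\n",
            100 * mean(dat$age < 20), 100 * mean(dat$age >= 35)))
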