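#!/usr/bin/env Rscript
# Stage 4: model-based probabilities for maternal profiles.
#
# Marginal, joint and conditional probabilities with 95% posterior-
# simulation intervals for a representative mother (26, White, tertiary
# education, married, non-smoker, not a first birth) and a high-risk mother
# (42, Black, primary education, unmarried, first birth), each with and
# without smoking.

suppressPackageStartupMessages(library(copbirth))

fit <- readRDS("results/fit.rds")

base_rep <- data.frame(ethnicity = "White", educ = "Tertiary",
                       firstbirth = 0, marital = 1, smoke = 0, age = 26,
                       county = "45")
base_high <- data.frame(ethnicity = "Black", educ = "Primary",
                        firstbirth = 1, marital = 0, smoke = 0, age = 42,
                        county = "45")
profiles <- list(
  representative = base_rep,
  representative_smoker = transform(base_rep, smoke = 1),
  high_risk = base_high,
  high_risk_smoker = transform(base_high, smoke = 1))

quantities <- c("marg1", "marg2", "joint11", "cond_1_given_2",
                "cond_1_given_not2", "cond_2_given_1", "theta", "tau")
rows <- NULL
for (pn in names(profiles)) {
  for (q in quantities) {
    r <- predict_quantity(fit, profiles[[pn]], q, n_sim = 1000, seed = 4)
    rows <- rbind(rows, data.frame(profile = pn, r))
  }
}
write.csv(rows, "results/profile_probabilities.csv", row.names = FALSE)

show <- subset(rows, quantity %in% c("marg1", "marg2", "joint11",
                                     "cond_1_given_2", "cond_1_given_not2"))
show$estimate <- sprintf("%.2f%%", 100 * show$estimate)
show$interval <- sprintf("(%.2f, %.2f)", 100 * show$lower, 100 * show$upper)
print(show[, c("profile", "quantity", "estimate", "interval")],
      row.names = FALSE)
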