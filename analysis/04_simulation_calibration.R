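#!/usr/bin/env Rscript
# Generator calibration: closure, error calibration, accessible fractions.
#
# Checks that the synthetic generator and the decomposition are exact
# inverses without noise, that the estimator's sampling SD matches the
# closed-form 2^(|S|/2) * sigma under unit noise, and reports the Monte
# Carlo distribution of the accessible-trajectory fraction for landscapes
# generated at the default spectral-tuning scale with a nonfunctional
# fraction comparable to the motivating system (60/127 ~ 0.47).

suppressPackageStartupMessages(library(lambdascape))
dir.create("results", showWarnings = FALSE)
set.seed(20260921)

# closure at zero noise
err <- 0
for (rep in 1:200) {
  sim <- generate_landscape(L = sample(2:5, 1), noise_sd = 0,
                            interaction_prob = runif(1, 0, 0.5),
                            seed = sample.int(2^30, 1))
  fit <- decompose(sim$landscape)
  err <- max(err, max(abs(fit$effects$theta -
                          sim$truth$theta[fit$effects$mask + 1])))
}
cat(sprintf("noise-free closure: max |theta_hat - theta| = %.2e nm over 200 specs\n", err))

# sampling SD of the estimates under unit noise, L = 3, 2000 replicates
est <- replicate(2000, {
  sim <- generate_landscape(L = 3, noise_sd = 1, interaction_prob = 0.3,
                            seed = sample.int(2^30, 1))
  fit <- decompose(sim$landscape)
  fit$effects$theta - sim$truth$theta[fit$effects$mask + 1]
})
ord <- c(1, 1, 1, 2, 2, 2, 3)
ratio <- apply(est, 1, sd) / 2^(ord / 2)
cat("empirical SD / theoretical SE by subset order:\n")
print(round(tapply(ratio, ord, mean), 3))

# accessible fraction at the default scale with ~47% nonfunctional
# genotypes, placed two ways: (a) i.i.d. across the lattice; (b) structured
# — every genotype carrying site s3 without its compensator s1 is
# nonfunctional (a single steric incompatibility), i.i.d. extras to 60.
frac_iid <- replicate(300, {
  sim <- generate_landscape(L = 7, nonfunctional_prob = 60 / 127,
                            seed = sample.int(2^30, 1))
  count_accessible(sim$landscape)$fraction_accessible
})
frac_struct <- replicate(300, {
  masks <- 1:127
  has3_no1 <- bitwAnd(masks, 4L) == 4L & bitwAnd(masks, 1L) == 0L  # 32 masks
  extra <- sample(masks[!has3_no1], 60 - sum(has3_no1))
  sim <- generate_landscape(L = 7, nonfunctional = c(masks[has3_no1], extra),
                            seed = sample.int(2^30, 1))
  count_accessible(sim$landscape)$fraction_accessible
})
for (nm in c("iid", "structured")) {
  frac <- if (nm == "iid") frac_iid else frac_struct
  cat(sprintf("accessible fraction, %s lethality (60/127 nonfunctional), 300 landscapes: median %.3f, IQR [%.3f, %.3f], max %.3f\n",
              nm, median(frac), quantile(frac, .25), quantile(frac, .75),
              max(frac)))
}
cat("structured (clustered) lethality leaves far more orderings accessible than\n")
cat("i.i.d. lethality at the same overall rate.\n")

jsonlite::write_json(
  list(noise_free_max_error = err,
       se_ratio_by_order = as.list(round(tapply(ratio, ord, mean), 4)),
       accessible_fraction_iid = list(median = median(frac_iid),
                                      q25 = unname(quantile(frac_iid, .25)),
                                      q75 = unname(quantile(frac_iid, .75))),
       accessible_fraction_structured = list(
         median = median(frac_struct),
         q25 = unname(quantile(frac_struct, .25)),
         q75 = unname(quantile(frac_struct, .75)))),
  "results/simulation_calibration.json", auto_unbox = TRUE, pretty = TRUE)
cat("wrote results/simulation_calibration.json\n")
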