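#!/usr/bin/env Rscript
# Clock-gene oscillations in synchronized fibroblast cultures: damped-cosine
# expression courses sampled 6-36 h after synchronization, 3 replicate
# cultures per group, analyzed by cosinor rhythmometry at a 24-h trial
# period. The attenuated-oscillation group should show a lower fitted
# amplitude than the control group.

library(actirhythm)

seed <- 20200601
times <- seq(6, 36, by = 3)

groups <- list(
  control = list(mesor = 1.0, amplitude = 0.50, acrophase = 18,
                 damping = 0.02, noise_sd = 0.06),
  dex = list(mesor = 1.0, amplitude = 0.15, acrophase = 18,
             damping = 0.05, noise_sd = 0.06)
)

dir.create("results", showWarnings = FALSE)
rows <- list(); courses <- list()
for (g in names(groups)) {
  p <- groups[[g]]
  ec <- simulate_expression(mesor = p$mesor, amplitude = p$amplitude,
                            acrophase_hours = p$acrophase, damping = p$damping,
                            noise_sd = p$noise_sd, sample_times = times,
                            replicates = 3, group = g,
                            seed = seed + match(g, names(groups)))
  fit <- cosinor_fit(ec, trial_period = 24)
  courses[[g]] <- ec
  rows[[g]] <- data.frame(group = g, gene = "Bmal1",
                          mesor = round(fit$mesor, 4),
                          amplitude = round(fit$amplitude, 4),
                          acrophase = round(fit$acrophase_zt, 3),
                          percent_rhythm = round(fit$percent_rhythm, 4),
                          n = fit$n)
}
out <- do.call(rbind, rows)
write.csv(do.call(rbind, courses), "results/expression_courses.csv", row.names = FALSE)
write.csv(out, "results/expression_cosinor.csv", row.names = FALSE)
print(out, row.names = FALSE)
cat(sprintf("amplitude ratio dex/control: %.2f\n",
            out$amplitude[out$group == "dex"] / out$amplitude[out$group == "control"]))
cat("written: results/expression_cosinor.csv\n")
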