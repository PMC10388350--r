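#!/usr/bin/env Rscript
# Stage 2: photon-by-photon hidden Markov analysis. Fits all four
# conditions globally with shared FRET efficiencies (4 states), writes the
# fitted models (JSON) and a comparison of recovered efficiencies and
# stationary populations against the generating values.

suppressPackageStartupMessages(library(fretstates))

seed <- 20260927L
n_bursts <- 2000
out_dir <- "results/fits"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

conditions <- c("apo", "atp", "adp", "atp_es")
rec <- run_global_recovery(conditions, n_bursts = n_bursts, seed = seed,
                           K = 4, restarts = 8)

cat("shared efficiencies (recovered vs generating):\n")
truth_e <- rec$truth$apo$efficiencies
print(data.frame(state = 1:4, recovered = round(rec$efficiencies, 4),
                 generating = truth_e))

pop_rows <- list()
for (cond in conditions) {
  m <- rec$fit$models[[cond]]
  write_h2mm_model(m, file.path(out_dir, paste0(cond, "_model.json")))
  pop_rows[[cond]] <- data.frame(
    condition = cond, state = 1:4,
    population = steady_state(m$rate_matrix),
    generating = rec$truth[[cond]]$initial_distribution
  )
}
pops <- do.call(rbind, pop_rows)
write.csv(pops, file.path(out_dir, "populations.csv"), row.names = FALSE)
write.csv(data.frame(state = 1:4, efficiency = rec$efficiencies,
                     generating = truth_e),
          file.path(out_dir, "efficiencies.csv"), row.names = FALSE)

cat("\nstationary populations by condition (recovered vs generating):\n")
print(within(pops, {
  population <- round(population, 3)
  generating <- round(generating, 3)
}))
cat("\nfit:", rec$fit$n_iterations, "EM iterations, converged:",
    rec$fit$converged, "\n")
cat("wrote models and tables under", out_dir, "\n")
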