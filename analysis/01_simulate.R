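#!/usr/bin/env Rscript
# Stage 1: generate the synthetic photon-trajectory datasets for the four
# solution conditions of the GroEL subunit (apo, 1 mM ATP, 1 mM ADP,
# ATP + GroES), write them in the columnar photon-stream format together
# with burst tables, and summarize the burst statistics.
#
# The ground-truth models use the published microstate FRET efficiencies
# (0.850, 0.608, 0.419, 0.213), the published stationary populations per
# condition, and an exchange construction k_ij = c pi_j with c = 3000 1/s
# (relaxation ~333 us, inside the observed 300-500 us window).

suppressPackageStartupMessages(library(fretstates))

seed <- 20260927L
n_bursts <- 2000
out_dir <- "results/datasets"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

conditions <- c("apo", "atp", "adp", "atp_es")
summary_rows <- list()
for (i in seq_along(conditions)) {
  cond <- conditions[i]
  sim <- simulate_condition(cond, n_bursts, stage_seed(seed, i))
  write_photon_stream(sim$dataset$stream,
                      file.path(out_dir, paste0(cond, "_photons.csv")))
  write_burst_table(sim$dataset$bursts,
                    file.path(out_dir, paste0(cond, "_bursts.csv")))
  jsonlite::write_json(
    list(condition = cond, seed = stage_seed(seed, i),
         efficiencies = sim$model$efficiencies,
         stationary = sim$model$initial_distribution,
         rate_matrix_s_inv = sim$model$rate_matrix,
         burst_duration_mean_s = sim$model$burst_duration_mean,
         photon_rate_hz = sim$model$photon_rate,
         n_bursts = n_bursts),
    file.path(out_dir, paste0(cond, "_truth.json")),
    auto_unbox = TRUE, digits = NA)
  h <- fret_histogram(sim$dataset$bursts, n_bins = 40)
  write.csv(h, file.path(out_dir, paste0(cond, "_fret_histogram.csv")),
            row.names = FALSE)
  b <- sim$dataset$bursts
  summary_rows[[cond]] <- data.frame(
    condition = cond, n_bursts = nrow(b),
    mean_photons = mean(b$n_dd + b$n_da + b$n_aa),
    mean_duration_ms = 1000 * mean(b$duration_s),
    mean_e = mean(b$e_raw, na.rm = TRUE),
    mode_e = h$bin_center[which.max(h$count)]
  )
  cat(sprintf("%-7s %d bursts, mean E %.3f, histogram mode %.3f\n",
              cond, nrow(b), summary_rows[[cond]]$mean_e,
              summary_rows[[cond]]$mode_e))
}
summary_df <- do.call(rbind, summary_rows)
write.csv(summary_df, file.path(out_dir, "burst_summary.csv"),
          row.names = FALSE)

# The apo histogram mode sits in the broad ~0.55 region and the ATP+GroES
# histogram shifts toward low efficiency, mirroring the condition-dependent
# population shifts the analysis is designed to resolve.
cat("wrote datasets and burst summaries under", out_dir, "\n")
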