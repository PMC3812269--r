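#!/usr/bin/env Rscript
# Step 2 -- aggregation kinetics of six fullerenes in bulk solvent.
#
# Ten seeded 100-ns Langevin runs of 6 single-site fullerenes under the
# effective pair potential; per run, the 1-ns block-averaged largest-cluster
# size and the lifetimes of transient 2-3 particle nuclei.

suppressPackageStartupMessages(library(fullermem))
dir.create("results", showWarnings = FALSE)

pot <- build_effective_potential(n_orientations = 100, seed = 1)

all_series <- list()
all_lifetimes <- list()
n_reach6 <- 0L
for (sd in 1:10) {
  traj <- simulate_aggregation(aggregation_params(seed = sd), pot)
  s <- largest_cluster_series(traj, cutoff = 0.6, block = 1000)
  s$run <- sd
  all_series[[sd]] <- as.data.frame(s)
  lt <- nucleus_lifetimes(s)
  if (nrow(lt)) { lt$run <- sd; all_lifetimes[[length(all_lifetimes) + 1]] <- lt }
  reached <- max(s$largest_size) >= 6
  if (reached) n_reach6 <- n_reach6 + 1L
  cat(sprintf("run %2d: final largest cluster %.1f, reached 6: %s\n",
              sd, tail(s$largest_size, 1), reached))
}
series <- do.call(rbind, all_series)
write.csv(series, "results/aggregation_series.csv", row.names = FALSE)

cat(sprintf("\n%d / 10 runs assembled all six fullerenes into one cluster\n",
            n_reach6))
if (length(all_lifetimes)) {
  lt <- do.call(rbind, all_lifetimes)
  write.csv(lt, "results/nucleus_lifetimes.csv", row.names = FALSE)
  cat(sprintf("2-3 particle nuclei: %d events, mean lifetime %.1f ns\n",
              nrow(lt), mean(lt$duration[!lt$censored]) / 1000))
}
cat("Series written to results/aggregation_series.csv\n")
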