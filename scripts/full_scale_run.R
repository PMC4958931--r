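#!/usr/bin/env Rscript
# Optional long-running regression: the full-scale 45 x 45 experimental
# track (three 15-cycle phases, 7 x 7 patches, receptive-field map at the
# end of each phase).  Expect one to a few hours on a single core.
#
#   Rscript scripts/full_scale_run.R [--seed 1] [--out-dir runs/full45]
#
# Writes per-phase network snapshots, receptive-field tables, the
# divergence grid, and a summary of band widths and border-centroid counts
# (the four-row divergent band straddling each digit boundary, and the
# within- vs across-digit weight contrast of boundary-adjacent columns such
# as #648).

args <- commandArgs(trailingOnly = TRUE)
seed <- 1L; out_dir <- "runs/full45"
i <- 1L
while (i <= length(args)) {
  if (args[i] == "--seed") { seed <- as.integer(args[i + 1L]); i <- i + 2L }
  else if (args[i] == "--out-dir") { out_dir <- args[i + 1L]; i <- i + 2L }
  else stop("unknown argument: ", args[i])
}

library(somatomap)
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

set.seed(seed)
spec <- lattice_spec(45)
net <- somatonet(spec)
track <- run_track(net, "experimental", n_cycles = 15, rf_every = 15,
                   verbose = TRUE)

for (nm in names(track$phases)) {
  p <- track$phases[[nm]]
  save_network(p$net, file.path(out_dir, paste0("net_", nm)))
  m <- p$rf_maps[[length(p$rf_maps)]]
  write_rf_map(m, file.path(out_dir, paste0("rf_", nm, ".csv")))
  write_divergence_grid(m, file.path(out_dir, paste0("divergence_", nm, ".csv")))
  cat("==", nm, "==\n")
  print(divergence_band_width(m, spec))
  bc <- centroid_border_cells(m, spec)
  print(data.frame(boundary = bc$boundary, border_E_centroids = bc$n))
}

# boundary-adjacent column #648 (row 15, col 18): within- vs across-digit
# lateral excitatory weight contrast after baseline refinement
base_net <- track$phases$baseline$net
wee <- incoming_weights(base_net, 15, 18, "EE")
rows <- 12:18                      # lattice rows spanned by the 7 x 7 mask
same_digit <- rows <= 15
w_within <- wee[same_digit, ]
w_across <- wee[!same_digit, ]
cat(sprintf("column 648 EE within-digit max/min: %.2f\n",
            max(w_within, na.rm = TRUE) / min(w_within, na.rm = TRUE)))
cat(sprintf("column 648 EE across/within min ratio: %.1f\n",
            max(w_within, na.rm = TRUE) / min(w_across, na.rm = TRUE)))
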