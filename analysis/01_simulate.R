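#!/usr/bin/env Rscript
# Step 1: generate the synthetic heart-tube scenario suite.
#
# Five seeded datasets emulating a ~10 h (46 frames x ~13 min) two-photon
# timelapse of the looping zebrafish heart tube, written as canonical track
# CSVs with JSON ground-truth sidecars under results/fixtures/:
#   wt_like      - ventricle spins -8 deg/h, atrium +6 deg/h (opposite
#                  rotation => twisting), 1 um noise
#   oug_like     - no imposed spin, noise only (the mutant-like null)
#   bending_only - 30 deg planar hinge swing, no spin, no noise (the
#                  buckling confound the unfolding must reject)
#   drift_only   - whole-heart translation drift only
#   noise_sweep  - wt-like kinematics at doubled (2 um) noise

library(cardiotwist)

out_dir <- file.path("results", "fixtures")
paths <- make_fixture_suite(out_dir, seed = 20260924L)

cat("wrote", length(paths), "scenario datasets to", out_dir, "\n")
for (nm in names(paths)) {
  ts <- read_tracks(paths[[nm]])
  cat(sprintf("  %-13s %3d tracks, %2d frames\n", nm,
              length(unique(ts$records$track_id)),
              length(unique(ts$records$t_index))))
}
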