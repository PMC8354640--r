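#!/usr/bin/env Rscript
# Step 2: hinge-rooted unfolding and rotation/twist quantification.
#
# Runs the full pipeline (15-point track filter, AV-centroid rooting,
# per-frame unfolding to the first-frame axes, per-cell signed angles,
# chamber-mean angular velocity, cumulative rotation, twisting) on the
# wt-like and mutant-like datasets from step 1 and on the bending-only
# confound. Tidy CSVs land in results/<scenario>/.

library(cardiotwist)

fix_dir <- file.path("results", "fixtures")
if (!dir.exists(fix_dir)) stop("run analysis/01_simulate.R first")

endpoint <- function(rs) rs$cum_angle_deg[nrow(rs)]

for (scenario in c("wt_like", "oug_like", "bending_only")) {
  ts <- read_tracks(file.path(fix_dir, paste0(scenario, ".csv")))
  res <- run_pipeline(ts, out_dir = file.path("results", scenario))
  cat(sprintf(
    "%-13s Theta_V(end) = %+7.2f deg  Theta_A(end) = %+7.2f deg  twist(end) = %+7.2f deg\n",
    scenario,
    endpoint(res$rotation$ventricle),
    endpoint(res$rotation$atrium),
    tail(res$twist$series$twist_angle_deg, 1)))
}

cat("\nExpected from the imposed kinematics: wt_like recovers ~(-78, +58.5,",
    "+136.5); oug_like stays near zero; bending_only must be ~0 in both",
    "chambers - apparent rotation there would mean planar buckling leaks",
    "into the twist estimate.\n")
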