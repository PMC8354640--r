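#!/usr/bin/env Rscript
# Step 3: replicate-level group comparisons.
#
# Simulates five wt-like and five mutant-like hearts (independent seeds),
# summarises each replicate's chamber angular velocity per 1.5 h window,
# and compares chambers and genotypes with rank-sum tests Bonferroni-
# corrected over the prespecified comparison set, plus a t-test and
# Mann-Whitney on the end-point twisting angle. Outputs:
#   results/replicate_windows.csv  - tidy per-replicate window table
#   results/comparisons.csv        - rank-sum + Bonferroni results
#   results/twist_endpoints.csv    - per-replicate final twisting angle

library(cardiotwist)

n_rep <- 5L
base_seed <- 52600L

simulate_replicate <- function(genotype, rep_id) {
  om <- if (genotype == "wt") c(-8, 6) else c(0, 0)
  params <- synthetic_heart_params(
    omega_ventricle_deg_h = om[1], omega_atrium_deg_h = om[2],
    seed = base_seed + rep_id + 100L * (genotype == "oug"))
  res <- suppressWarnings(suppressMessages(
    run_pipeline(generate_heart(params)$tracks)))
  w <- res$windows[!res$windows$partial &
                   res$windows$series %in% c("ventricle", "atrium"), ]
  list(
    windows = data.frame(replicate = sprintf("%s_%d", genotype, rep_id),
                         group = genotype, chamber = w$series,
                         window = w$window,
                         value = w$mean_omega_deg_per_h),
    twist_end = tail(res$twist$series$twist_angle_deg, 1)
  )
}

reps <- unlist(lapply(c("wt", "oug"), function(g) {
  lapply(seq_len(n_rep), function(i) simulate_replicate(g, i))
}), recursive = FALSE)
windows <- do.call(rbind, lapply(reps, `[[`, "windows"))
twist_end <- data.frame(
  replicate = vapply(reps, function(r) r$windows$replicate[1], character(1)),
  group = vapply(reps, function(r) r$windows$group[1], character(1)),
  twist_end_deg = vapply(reps, `[[`, numeric(1), "twist_end"))

dir.create("results", showWarnings = FALSE)
write.csv(windows, "results/replicate_windows.csv", row.names = FALSE)
write.csv(twist_end, "results/twist_endpoints.csv", row.names = FALSE)

# Replicate-level mean angular velocity per chamber x genotype
windows$cell <- paste(windows$group, windows$chamber, sep = ".")
rep_means <- aggregate(value ~ replicate + cell, data = windows, FUN = mean)
names(rep_means)[names(rep_means) == "cell"] <- "group"

comparisons <- list(
  c("wt.ventricle", "wt.atrium"),       # opposite rotation in wt
  c("oug.ventricle", "oug.atrium"),     # no separation in the mutant
  c("wt.ventricle", "oug.ventricle"),
  c("wt.atrium", "oug.atrium")
)
cmp <- ranksum_bonferroni(rep_means, comparisons)
write.csv(cmp, "results/comparisons.csv", row.names = FALSE)

cat("replicate-level rank-sum comparisons (Bonferroni over",
    length(comparisons), "tests):\n")
print(cmp, row.names = FALSE)

tw <- ttest_two_sample(twist_end$twist_end_deg[twist_end$group == "wt"],
                       twist_end$twist_end_deg[twist_end$group == "oug"])
mw <- mannwhitney_u(twist_end$twist_end_deg[twist_end$group == "wt"],
                    twist_end$twist_end_deg[twist_end$group == "oug"])
cat(sprintf("\nfinal twisting angle, wt vs mutant-like: t = %.2f (p = %.4g), Mann-Whitney U = %g (p = %.4g)\n",
            tw$t, tw$p, mw$U, mw$p))
cat("The wt chambers separate (ventricle negative, atrium positive);",
    "the spin-free mutant-like hearts do not, and their twisting angle",
    "stays near zero.\n")
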