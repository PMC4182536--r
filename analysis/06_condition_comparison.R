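#!/usr/bin/env Rscript
# Wild-type vs alanine-mutant comparison through the one-call pipeline:
# per-residue contact-probability drops, RMSF and helix-fraction deltas,
# and the shift of the compactness mixture.

source("analysis/00_conditions.R")

out <- results_dir("comparison")

wild <- generate_dimer_trajectory(conditions$wild)$trajectory
mutant <- generate_dimer_trajectory(conditions$mutant)$trajectory

rep_w <- run_pipeline(run_config(list(wild), contact_surface_frames = 0,
                                 mixture = list(k = 2, seed = SEED + 20L,
                                                n_starts = 5)),
                      verbose = FALSE)
rep_m <- run_pipeline(run_config(list(mutant), contact_surface_frames = 0,
                                 mixture = list(k = 2, seed = SEED + 21L,
                                                n_starts = 5)),
                      verbose = FALSE)
cmp <- compare_conditions(rep_w, rep_m)

write.csv(cmp$contact_delta, file.path(out, "contact_delta.csv"),
          row.names = FALSE)
write.csv(cmp$rmsf_delta, file.path(out, "rmsf_delta.csv"),
          row.names = FALSE)
write.csv(cmp$helix_delta, file.path(out, "helix_delta.csv"),
          row.names = FALSE)

message("largest contact-probability changes (wild -> mutant):")
top <- head(cmp$contact_delta[cmp$contact_delta$delta != 0, ], 6)
for (i in seq_len(nrow(top))) {
  message(sprintf("  residue %3d: %2.0f%% -> %2.0f%%  (delta %+3.0f%%)",
                  top$resid[i], 100 * top$probability_a[i],
                  100 * top$probability_b[i], 100 * top$delta[i]))
}
message(sprintf("compactness mixture shift: %+0.3f / %+0.3f nm",
                cmp$rg_fit_delta$means[1], cmp$rg_fit_delta$means[2]))
message("the interface residues lose most of their contact involvement;")
message("the C-terminal tail takes over the mutant interface")
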