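#!/usr/bin/env Rscript
# Generate the three synthetic study conditions and record their ground
# truth. Trajectories are regenerated deterministically by the later
# scripts (same spec + seed), so only the small truth tables are kept.

source("analysis/00_conditions.R")

out <- results_dir("truth")
for (nm in names(conditions)) {
  gen <- generate_dimer_trajectory(conditions[[nm]])
  write.csv(gen$truth$frames, file.path(out, paste0(nm, "_frames.csv")),
            row.names = FALSE)
  if (!is.null(gen$truth$contacts)) {
    write.csv(gen$truth$contacts, file.path(out, paste0(nm, "_contacts.csv")),
              row.names = FALSE)
  }
  tr <- gen$trajectory
  message(sprintf("%-6s: %d frames, %d atoms, chains %s", nm, n_frames(tr),
                  n_atoms(tr), paste(unique(tr$topology$chain),
                                     collapse = "+")))
}
message("ground truth written under ", out)
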