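# Shared study conditions for the analysis scripts. Sourced, not run.
#
# Three seeded synthetic conditions stand in for the MD ensembles:
#   wild   - bound dimer: interface plan Arg101 65% (vs Asp57), Lys128 55%,
#            Asp145 50%, C-terminal Leu178/Arg182 40%; bimodal monomer
#            compactness 1.73/1.65 nm; 35% helix-coil switching of the
#            84-87 block with coupled solvent exposure.
#   mutant - Ala101/Ala103 dimer: 25/18/18%, C-terminal 60%; compactness
#            1.71/1.61 nm; helix conserved.
#   single - lone monomer: unimodal 1.71 nm (sd 0.03); helix conserved.

library(dimerlens)

SEED <- 1234L
N_FRAMES <- 200L

conditions <- list(
  wild = default_plant_spec("bound", seed = SEED, n_frames = N_FRAMES),
  mutant = default_plant_spec("mutant", seed = SEED + 1L,
                              n_frames = N_FRAMES),
  single = default_plant_spec("single", seed = SEED + 2L,
                              n_frames = N_FRAMES)
)

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
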