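# dimerlens

Post-processing toolkit for protein dimerization ensembles: per-residue
inter-monomer contact probability, contact maps and interface tables,
Shrake–Rupley solvent-accessible surface and buried contact surface, Kabsch
superposition with RMSD/RMSF profiles, radius-of-gyration mixture
decomposition into open/closed hairpin states, backbone dihedrals with
Ramachandran classification, and a hydrogen-bond based secondary-structure
assigner — plus a seeded synthetic trajectory generator that plants all of
those signals with known ground truth.

The package is aimed at structural bioinformaticians characterizing
protein–protein association from coordinate ensembles. The motivating
system is the Josephin Domain (JD) of ataxin-3, whose self-association
seeds the aggregation behind spinocerebellar ataxia type 3: the analyses
here answer which residues carry the JD–JD interface, whether binding
shifts the monomer between its open (~1.73 nm radius of gyration) and
closed (~1.65 nm) hairpin conformations, and whether helix alpha-4
(Leu84–Trp87) unfolds and moves toward the solvent upon binding.

## The core statistic

For residue *i* of monomer A against partner monomer B over *T* snapshots:

```
c_i(t) = 1[ min_{j in B} d_ij(t) <= r_c ],      p_i = (1/T) * sum_t c_i(t)
```

`d_ij` is the minimum atom–atom distance between residues *i* and *j*, and
`r_c = 0.28 nm` (about one water diameter; the threshold is inclusive).
Probabilities are exact rationals — integer contact counts over integer
snapshot counts. Supporting observables: `RG = sqrt(sum m_k |r_k - r_com|^2
/ sum m_k)` decomposed by a two-component Gaussian EM fit, per-residue
`RMSF_i = sqrt(<|r_i - <r_i>|^2>)` after two-pass mass-weighted Kabsch
superposition on the globular core, Kabsch–Sander hydrogen-bond
secondary structure reduced to helix/sheet/coil, and the buried surface
`CS = (SAS_A + SAS_B - SAS_AB) / 2`.

## Worked example

Generate the bound-dimer study condition (a two-chain synthetic ensemble
with a planted interface and a bimodal monomer compactness) and analyse it:

```r
library(dimerlens)

gen  <- generate_dimer_trajectory(default_plant_spec("bound", seed = 1234,
                                                     n_frames = 200))
tr   <- gen$trajectory

cp   <- contact_probability(tr, "A", "B", cutoff = 0.28)
head(cp$a[order(-cp$a$probability), c("resname", "resid", "probability")], 5)
#>     resname resid probability
#> 101     ARG   101        0.65
#> 128     LYS   128        0.55
#> 145     ASP   145        0.50
#> 178     LEU   178        0.40
#> 182     ARG   182        0.40

rg   <- rg_series(tr, which(tr$topology$chain == "A"))
fit  <- fit_gaussian_mixture(rg$values, k = 2, seed = 1244)
fit
#> <mixture_fit> k = 2, logLik = 382.3135 (converged, 25 iter)
#>   component 1: weight 0.489, mean 1.7330, sd 0.0189
#>   component 2: weight 0.511, mean 1.6538, sd 0.0187
```

Arg101 heads the interface (in contact in 65% of snapshots, paired with
Asp57 of the partner — a salt bridge, both classed charged in
`interface_table()`), and the bound monomer's compactness splits into an
open-like component near 1.73 nm and a closed-like component near 1.65 nm.
Classifying frames by those fitted centres:

```r
st <- classify_states(rg, open_center = fit$means[1],
                      closed_center = fit$means[2], band = min(fit$sds))
table(st$labels)
#>       closed intermediate         open
#>           84           34           82
```

The numbered scripts under `analysis/` run this battery end to end —
simulation of the three study conditions (wild-type-like dimer,
Ala101/Ala103 mutant, lone monomer), interface, conformation,
fluctuations, secondary structure, and the wild-vs-mutant comparison —
writing their tables under `results/` and narrating what they find; e.g.
`analysis/06_condition_comparison.R` prints:

```
largest contact-probability changes (wild -> mutant):
  residue 101: 65% -> 25%  (delta -40%)
  residue 128: 55% -> 18%  (delta -37%)
  residue 145: 50% -> 18%  (delta -32%)
  residue 178: 40% -> 60%  (delta +20%)
  residue 182: 40% -> 60%  (delta +20%)
```

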