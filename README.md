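# pepensemble

Analysis of conformational ensembles of intrinsically disordered peptides
sampled by replica-exchange molecular dynamics (REMD), built around the
31-residue amino-truncated Alzheimer's amyloid-β fragment Aβ10-40 as the
reference system.

Disordered peptides such as Aβ lack a native fold: their behavior is a
statistical property of a broad conformational ensemble, and simulated
ensembles depend on the force field that generated them. This package
implements the standard battery of structural probes used to characterize
and compare such ensembles:

- **Secondary structure.** A hydrogen-bond-pattern assigner (Kabsch–Sander
  electrostatic energy, E = 0.084·332·(1/r<sub>ON</sub> + 1/r<sub>CH</sub> −
  1/r<sub>OH</sub> − 1/r<sub>CN</sub>) kcal/mol, bond when E < −0.5)
  reduces each frame to four states — helix H (α, 3₁₀ or π), strand S
  (extended or isolated bridge), turn T, random coil RC — and ensemble
  propensities ⟨H(i)⟩, ⟨T(i)⟩, ⟨RC(i)⟩, ⟨S(i)⟩.
- **Tertiary structure.** Side-chain contact maps ⟨C(i,j)⟩: a contact forms
  when side-chain heavy-atom geometric centers lie within 6.5 Å (strict),
  classified long-range when |j − i| ≥ 5; top-ranked and stable
  (⟨C(i,j)⟩ > 0.35) contact tables; mean contact counts ⟨C⟩ and ⟨C_LR⟩.
- **Backbone fluctuations.** Circular (wrap-aware) RMS fluctuations δφ(i),
  δψ(i) of the backbone dihedrals.
- **Compactness.** Radius of gyration over side-chain mass centers plus Cα
  atoms, its distribution P(R_g), and the end-to-end distance ⟨R_1N⟩.
- **NMR observables.** ³J(HN-Hα) couplings via the Karplus relation
  J = A·cos²(φ−60°) + B·cos(φ−60°) + C with the Pardi, Brueschweiler and
  Vuister coefficient sets; residual dipolar couplings via a steric
  parallel-plate obstruction model that yields a symmetric traceless
  alignment tensor, followed by least-squares scaling against experiment.
- **Experiment agreement.** RMSD, Pearson correlation, and the quality
  factor Q = √[Σ(D<sub>comp</sub>−D<sub>exp</sub>)² / ΣD<sub>exp</sub>²],
  evaluated per experimental-table × Karplus-set combination.
- **Reweighting.** Binless WHAM over canonical replica energy records:
  self-consistent dimensionless free energies per temperature and pooled
  frame weights at any target temperature (330 K for structure, 300 K for
  J/RDC by default), with multi-trajectory error bars.
- **Synthetic data.** A generator that builds dihedral-sampled peptide
  ensembles with controllable helix/strand/turn/coil content from ideal
  internal coordinates, replica energy records on an exponential
  300–440 K ladder, and noisy synthetic "experimental" tables — so the
  whole pipeline runs and is tested end to end without simulation data.

## Worked example

Generate a synthetic random-coil run (50 frames per replica, four replica
temperatures), reweight it to 330 K with WHAM, and analyze it:

```r
library(pepensemble)

cfg <- default_config(seed = 7, out_dir = "demo_run", n_frames = 50,
                      temperatures = temperature_ladder(300, 440, 4))
run_generate(cfg)
ana <- run_analyze(cfg)
ana
#> pep_analysis run: demo_run
#>   <H>=0.018 <S>=0.005 <T>=0.208 <RC>=0.770 | <C>=13.7 (LR 5.2) | <Rg>=15.8 A

ana$wham
#> WHAM solution over 4 temperature(s), 200 pooled samples
#>   converged in 126 iteration(s), residual 9.38e-08
#>   T =  300.00 K   f =    0.00000
#>   T =  340.85 K   f =   18.06417
#>   T =  387.27 K   f =   29.74547
#>   T =  440.00 K   f =   36.17832

ana$top_long
#>   rank  i  j  occupancy range
#> 1    1 31 37 0.09023483  long
#> 2    2 19 24 0.07506682  long
#> 3    3 10 20 0.07033407  long
#> 4    4 23 28 0.06997724  long
#> 5    5 30 38 0.06920819  long

round(head(ana$jcoupling, 5), 3)
#>    11    12    13    14    15
#> 7.525 7.248 7.320 7.293 7.009
```

Reading the output: the coil generator produces an ensemble dominated by
random coil (⟨RC⟩ = 0.77) and turn (⟨T⟩ = 0.21) with negligible helix and
strand, about 14 side-chain contacts per frame of which ~5 are long-range,
and ⟨R_g⟩ ≈ 16 Å — an expanded, disordered ensemble. Contact occupancies
are all far below the 0.35 stability threshold, as expected for a random
coil. Per-residue ³J(HN-Hα) couplings near 7–7.5 Hz reflect the
extended/polyproline-II φ angles of the coil basins.

`run_analyze()` also writes every table (propensities, contact map, top
and stable contacts, RMSF, P(R_g), J-couplings, RDCs) as
provenance-stamped TSVs into `out_dir`; `run_compare()` adds
experiment-agreement (RMSD/PCC/Q) and run-similarity rankings. A thin
command-line wrapper lives at `inst/scripts/pepensemble-cli.R`
(subcommands `generate`, `analyze`, `compare`).

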