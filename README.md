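# terpQSAR

Quantitative structure– and property–activity modelling of essential-oil
terpenes and terpenoids as larvicides against *Culex quinquefasciatus*, the
southern house mosquito and a filariasis/arbovirus vector. The package is
aimed at cheminformaticians and vector-control researchers who want a fully
scripted, testable version of a classic small-molecule QSAR workflow:

* a hydrogen-depleted **molecular graph** model with its own SMILES parser
  and canonical writer (no external chemistry toolkit required);
* **constitutional** counts (nCs, nCt, nCconj, nRCO, nArOH, …),
  **topological** indices (Balaban J, unipolarity/centralization/variation,
  eccentric connectivity, centric BAC/Lop, radial centric information,
  Kier flexibility Φ, E-state values) and **physicochemical** descriptors
  (Ui, Todeschini Hy, Ertl TPSA, Moriguchi MlogP, Wildman–Crippen
  AlogP/AMR);
* **conceptual-DFT reactivity** descriptors from frontier-orbital energies
  via Koopmans' theorem: I = −E_HOMO, A = −E_LUMO, gap, χ = (I+A)/2,
  μ = −χ, hardness η = gap/2, softness σ = 1/η, electrophilicity ω = μ²/2η;
* a maximum-likelihood **probit** engine for grouped mortality data,
  P(death) = Φ(α + β·log₁₀ dose), with LC50 = 10^(−α/β), Fieller 95%
  intervals, Abbott control correction and a Proc-Probit-style
  heterogeneity factor;
* **OLS/QSAR machinery** with leave-one-out Q² = 1 − PRESS/TSS (hat-matrix
  identity, oracle-verified) and a **genetic algorithm** for descriptor
  subset selection (binary chromosomes, tournament selection, uniform
  crossover, elitism, fitness = Q²);
* **synthetic-data generators** for probit bioassays and planted-model
  descriptor matrices, so every stage is testable with known truth;
* the embedded **50-compound library** with experimental LC50 fixtures and
  verbatim transcriptions of the published descriptor tables, including
  `suspect` flags on rows whose printed values contradict the named
  structures.

A deliberate negative result is part of the package: the published
regression statistics (e.g. Model 1 R² = 0.828) are *not derivable* from
the published descriptor tables and activities — exhaustive subset
enumeration caps at R² ≈ 0.57 — so `evaluate_published_model()` reports
recomputed statistics beside the printed ones instead of pretending to
reproduce them. The analysis is laid out in `vignettes/methods.Rmd`.

## Worked example

```r
library(terpQSAR)

# topological profile of thymol, computed from its structure alone
topological_profile(parse_smiles("Cc1ccc(C(C)C)c(O)c1"))
#>      J    TIE   UNIP   CENT    VAR    BAC    Lop    ICR    CSI    ECC    PHI
#>  2.437 24.333 20.000 80.000 16.000 18.000  1.160  1.936 95.000 50.000  2.299
```

J, UNIP…ECC match the published row for thymol exactly; Φ = 2.299 vs the
printed 2.3. (TIE is the documented exception — see the vignette.)

```r
# Koopmans reactivity from p-anisaldehyde's orbital energies (eV)
koopmans_profile(-8.954, 2.096)
#>      I      A    gap    chi     mu    eta  sigma  omega
#>  8.954 -2.096 11.050  3.429 -3.429  5.525  0.181  1.064
```

gap = 11.050 eV, η = 5.525 eV and σ = 0.181 eV⁻¹ are the printed values.

```r
# probit LC50 from a grouped bioassay (5 doses x 20 larvae)
ds <- dose_response(c(10, 20, 40, 80, 160), rep(20, 5), c(2, 6, 11, 16, 19))
fit_probit(ds)
#> Probit fit: alpha = -3.6470, beta = 2.3731 (on log10 dose)
#> LC50 = 34.42  [25.29, 46.14]  (fieller, 95%)

# GA subset selection on synthetic data with a planted 3-descriptor model
sim <- gen_qsar(seed = 7)                      # 50 x 20, realized R2 ~ 0.85
ga <- ga_search(sim$X, sim$y, max_size = 3, pop_size = 60,
                generations = 60, seed = 7, n_best = 1)
ga[[1]]
#> MLR model: 50 compounds, 3 descriptors
#>   R2 = 0.863  Q2(LOO) = 0.834  s = 0.495  F = 96.4
#>     coefficient contribution
#> d3       0.9844       0.7709
#> d7      -0.8554      -0.7147
#> d12      0.6242       0.4458
```

The GA recovered the planted subset {d3, d7, d12}.

## Command line

```sh
Rscript -e 'terpQSAR::run_cli()' descriptors --in mols.smi --set topological --out desc.csv
Rscript -e 'terpQSAR::run_cli()' probit --in doses.csv --out fit.json
Rscript -e 'terpQSAR::run_cli()' reproduce --out report/ --seed 1
```

Exit codes: 0 success, 2 usage, 3 data validation, 4 non-convergence.

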