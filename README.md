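# rnafoldeq

Quantitative analysis of a slow two-state RNA secondary-structure
equilibrium from solution-NMR observables.

Group II intron domain 6 interconverts between two competing secondary
structures — a 1-nucleotide-bulge fold (**1B**) with the branch-site
adenosine bulged out, and a 2-nucleotide-bulge fold (**2B**) — on the slow
(tens of milliseconds) exchange time scale. The fold equilibrium is coupled
to the sugar pucker of the branch-site adenosine (C2′-endo, catalytically
active, in 1B; C3′-endo in 2B) and is shifted by Mg²⁺, EDTA and branching.
`rnafoldeq` implements the four quantitative analyses that characterize such
an equilibrium, for anyone fitting ZZ-exchange/T1 decay series, quantitative-J
coupling ratios, lineshape-based fold populations, or UV melting curves of
two-state RNA folds:

1. **Exchange kinetics.** Longitudinal magnetization of a residue exchanging
   between folds A ≡ 1B and B ≡ 2B evolves as *dM/dt = −A·M* with

   ```
   A = | k_f + R1_A    −k_b       |        λ₁,₂ = ½[−(a₁₁+a₂₂) ± √((a₁₁−a₂₂)² + 4 a₁₂a₂₁)]
       | −k_f          k_b + R1_B |
   ```

   The ZZ-exchange auto-peak curves `M_AA(t)/M_AA(0)`, `M_BB(t)/M_BB(0)` and
   the T1 curves `M_A(t)/M_A(0)`, `M_B(t)/M_B(0)` have closed biexponential
   forms in λ₁, λ₂; all four channels are fitted jointly for the four shared
   parameters (k_f, k_b, R1 of each fold) with Monte-Carlo uncertainties.
   Detailed balance converts rates to populations: p_1B = k_b/(k_f+k_b).

2. **Sugar pucker.** The quantitative-J H1′(C1′)H2′ experiment gives
   `S_cross/S_diag = −tan²(2π J ζ)` (ζ = 13.05 ms), inverted for
   ³J(H1′H2′); a two-state north/south model converts J to the C2′-endo
   fraction `(J − J_N)/(J_S − J_N)`.

3. **Fold populations.** `p_1B = V_1B/(V_1B + V_2B)` from per-fold peak
   volumes, or from areas of a two-Lorentzian lineshape fit to a 1D slice;
   trend reporting across titration conditions.

4. **Melting thermodynamics.** Linear-baseline transformation of absorbance
   to the association degree α(T), then the van't Hoff fit
   `α = 1/(1 + exp((ΔH° − TΔS°)/(RT)))` giving ΔH°, ΔS° and Tm = ΔH°/ΔS°.

A fully seeded synthetic-data generator (`scenario_config()`,
`gen_*()`, `generate_scenario()`) reproduces the statistical structure of
every input — including presets for the resting-state kinetics
(k_ex = 20.89, 15.24, 10.11, 7.88 s⁻¹ at 60/40 populations) and the
titration end points — so the entire pipeline is testable end to end.

## Worked example

```r
library(rnafoldeq)

cfg    <- scenario_config(seed = 20, snr = 100)   # resting-state preset
decays <- gen_exchange_dataset(cfg)
decays$mixing_time <- decays$mixing_time_ms / 1000

fit <- fit_exchange(dplyr::filter(decays, residue_id == "U24"))
fit <- monte_carlo_errors(fit, n_runs = 1000, seed = 20)
fit
#> <exchange_fit>
#>   k_f = 8.557, k_b = 12.53, r1_a = 2.527, r1_b = 2.547 s^-1
#>   k_ex = 21.09 s^-1, populations (1B/2B) = 0.594/0.406
#>   rss = 47.21 over 44 points, converged
#>   Monte-Carlo (n = 1000): k_ex sd = 0.44 s^-1
```

The fitted exchange rate (21.09 ± 0.44 s⁻¹) recovers the generating
k_ex = 20.89 s⁻¹ of the preset within one standard deviation, and the
detailed-balance populations (0.594/0.406) recover the generating 60/40
split. `tidy(fit)` returns the parameter table, `glance(fit)` a one-row
summary, `autoplot(fit)` the data with fitted curves.

```r
estimate_populations(gen_peak_tables(cfg))[, 1:4] |> dplyr::select(-probe)
#>   condition    p_1B  p_2B
#>   apo         0.603 0.397
#>   branched    0.244 0.756
#>   branched_mg 0.100 0.900
#>   edta_24eq   0.766 0.234
#>   mg_25eq     0.333 0.667

analyze_coupling(gen_coupling_table(cfg))
#>   residue_id  j_hz south_fraction status
#> 1 U12_1B       8.8          1     detected
#> 2 A23_1B       4.6          0.462 detected
#> 3 U12_2B       8.8          1     detected
#> 4 A23_2B      NA            0     C3'-endo (no detectable cross peak)
```

The coupling table reproduces the diagnostic conversions: a 4.6 Hz
³J(H1′H2′) coupling means 46% C2′-endo for the branch-site adenosine in
fold 1B, and an undetectable cross peak means an essentially pure C3′-endo
pucker in fold 2B. `run_pipeline()` drives all stages over a scenario
directory and writes JSON reports plus a summary CSV.

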