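# optocoop

Reaction–diffusion simulation and analysis of **light-patterned
cooperation** in yeast lawns growing on sucrose.

## The problem

When budding yeast grows on sucrose it must first hydrolyse it with the
periplasmic invertase Suc2p; the resulting hexoses leak into the medium
and become a *public good* that any neighbouring cell can consume. Put
invertase expression under optogenetic control and a projected light
pattern paints a landscape of **cooperators** (illuminated, producing the
enzyme at a cost) and **cheaters** (dark, free-riding on the shared
hexoses). The striking result is that the benefit of cooperating depends
on the *size* of the cooperator domains: the system acts as a spatial
bandpass filter. Domains narrower than a lower cut-off λ− lose their
hexoses to the surrounding cheaters; domains wider than an upper cut-off
λ+ starve in their interior because the sucrose reservoir held by the
cheater regions cannot diffuse deep enough in.

`optocoop` is aimed at quantitative microbial ecologists and synthetic
biologists who want to explore those length scales numerically: it
implements the coupled PDE model, the illumination-pattern generators,
the readouts used to quantify cooperation, and a synthetic plate-scanner
observation model so the entire analysis pipeline runs without any
experimental data.

## The model

Fields on a 1D or 2D grid (thin-gel approximation): sucrose `S`, hexose
`H` (mol/L), immobile periplasmic invertase `E` (mol/L of gel), cell
density `N` (CFU/mL), cumulative uptake `U`. With N′ the density in
cells/L and α(x) set by the light pattern,

    ∂S/∂t = D_S ∇²S − v                 v = k_cat·E·S/(K_S+S) + k_spont·S
    ∂H/∂t = D_H ∇²H + 2φv − u           u = N′·[V_hi·H/(K_hi+H) + V_lo·H/(K_lo+H)]
    ∂E/∂t = α(x)·N′ − δ_E·E
    ∂N/∂t = µ_max·H/(K_H+H)·N
    ∂U/∂t = u + 2(1−φ)v

so that `2S + H + U` is an exact invariant (one sucrose → two hexoses).
The fitted rates are α_coop = 1.8e−24 and α_cheat = 1.5e−25
mol s⁻¹ cell⁻¹ with µ_max = 0.27 h⁻¹; the remaining constants are
clearly-labelled literature placeholders (see the methods vignette in
`vignettes/spatial-cooperation.Rmd` and `params_dump()`).

The solver is tolerance-controlled (Strang splitting: Crank–Nicolson
diffusion + embedded RK23 kinetics) and is cross-checked against an
independent well-mixed Cash–Karp integrator (`run_0d()`), an analytic
heat-kernel limit, and an exact mass audit.

## Worked example

Simulate a single 5.6 mm line of light on a 40 mm lawn and look at the
centre of the illuminated stripe:

```r
library(optocoop)
g   <- rd_grid(40, spacing = 0.1)              # 40 mm, 0.1 mm cells
pat <- light_single_line(g, w = 5.6, center = 20)
tr  <- integrate_rd(initial_state(g), pat, kinetic_params(),
                    t_end = 25, out_times = c(15, 25))
pr15 <- density_profile(tr, 15); pr25 <- density_profile(tr, 25)
sprintf("N at line center: %.3g (15 h) -> %.3g (25 h) CFU/mL",
        pr15$N[200], pr25$N[200])
#> "N at line center: 1.8e+07 (15 h) -> 2.54e+08 (25 h) CFU/mL"
```

The lawn starts at 1e6 CFU/mL; by 25 h the illuminated cells have grown
~250-fold while sucrose under the stripe has dropped from 29.2 mM to
8.5 mM — the stripe is becoming a sucrose sink fed by the dark flanks.

The headline analysis is the wavelength sweep (stripes at constant 25%
duty cycle, evaluated at 40 h; ~90 s on one CPU):

```r
sw <- benefit_sweep(c(2.5, 5, 7.5, 10, 15, 20, 25, 30, 40),
                    kinetic_params())
cutoff_wavelengths(sw)
#> bandpass cut-offs at 70% of B_max = 1.035e+09 CFU/mL (peak at 10 mm):
#>   lambda- = 3.64 mm
#>   lambda+ = 15.5 mm
```

`B` is the *cooperator benefit* — cell density at the centre of a lit
stripe minus the centre of a dark stripe. The bell-shaped `B(λ)` with
cut-offs at roughly 4 and 16 mm is the bandpass behaviour described
above.

## Command line

A single executable with subcommands (`exec/optocoop`):

```sh
optocoop simulate --config run.yaml --out out/      # trajectory + metrics CSVs
optocoop sweep    --config run.yaml --lambda 5,10 --lambda 20 --out sw/
optocoop synth    --config run.yaml --seed 7 --out synth/   # scanner frames + truth
optocoop analyze  --frames synth/frames --out metrics/
optocoop params dump --config run.yaml              # resolved key=value set
```

Configs are YAML (unknown keys rejected); every output directory gets
the resolved config with a stable content hash and the parameter
provenance dump. Exit codes: 0 ok, 2 config error, 3 numerical failure.

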