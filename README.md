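# photoxl

Quantitative analysis of alkyl-diazirine photo-cross-linking (PXL) for
structural proteomics.

Alkyl diazirines — as in the heterobifunctional cross-linker SDA, whose
NHS ester conjugates to Lys amines while the diazirine photo-reacts with
a nearby residue — open under ~365 nm light into two very different
intermediates: a **diazo** species that reacts selectively with polar,
nucleophilic side chains (Asp, Glu, Tyr, Ser, ...) and a **carbene** that
inserts promiscuously and is instantly quenched by water. Whether PXL
yields clean residue-specific distance restraints or a heterogeneous
smear depends on which intermediate does the chemistry, and that balance
is set by the optical power density `[hv]` (mW/cm²) and the irradiation
time `t`. This package is for mass spectrometrists and structural
biologists who want to put numbers on that balance: fit the photolysis
kinetics, decide the mechanism, choose irradiation conditions, and map
the resulting cross-links onto structures with honest over-length
accounting.

## The models

**Photolysis kinetics.** Four candidate schemes connect diazirine *A*,
diazo *B*, carbene *C* and the monitored product *D*. The general scheme
(model II) is

    A --k1[hv]--> B --k2'[hv]--> C,   A --k3[hv]--> C

with closed forms (λ_A = (k1+k3)[hv], λ_B = k2'[hv]):

    A(t) = A0 exp(-λ_A t)
    B(t) = k1 A0/(k1-k2'+k3) · (exp(-λ_B t) - exp(-λ_A t))
    D(t) = φ_D A0 (1 - k1/(k1-k2'+k3) exp(-λ_B t)
                     + (k2'-k3)/(k1-k2'+k3) exp(-λ_A t))

Model I sets k3 = 0, model III makes B→C light-independent, model IV
sets k2 = 0 (single-exponential D). `discriminate_models()` implements
the exclusion logic (lack-of-fit F-test, power invariance on the λ_A·t
axis, branching ratio k1/(k1+k3) from the joint fit).

**Residue reactivity.** Adduct yield decomposes into five elementary
channels, `yield = b1·I_b1 + b2·I_b2 + b3·I_b3 + b4·I_b4 + c·I_c`
(diazo with protonated/deprotonated target, their proton-catalyzed
counterparts, and carbene insertion). The mechanism score
`b1+b2+b3+b4-c ∈ [-1, 1]` classifies a residue as diazo- (positive) or
carbene-targeted (negative). Channel shapes are competition-kinetics
forms built on the model-II solution — every diazo channel peaks at an
interior power density, the carbene channel grows monotonically — so
scanning `[hv]` at fixed `t` identifies the weights.

**Distance mapping.** Cross-links are judged against
`max_allowed = reach(res1) + spacer + reach(res2)` (spacer 3.9 Å for
SDA); the normalized distance `calc − max_allowed` is negative for
satisfied links, and `over_length` is exactly `normalized > 0`.
Enrichment over natural abundance, Shrake–Rupley solvent accessibility
and precursor-mass-error comparisons complete the picture.

## Worked example

Simulate MRM traces at two powers under model II with the fitted
per-photon coefficients (k1+k3 = 2.32×10⁻⁴ cm²/(mW·s),
k2 = 0.73×10⁻⁴ cm²/(mW·s), branching ratio 0.92), then let the package
work out the mechanism from the data alone:

```r
library(photoxl)

kin <- photolysis_params(k1 = 0.92 * 2.32e-4, k2 = 0.73e-4,
                         k3 = 0.08 * 2.32e-4)
traces <- simulate_mrm_traces("II", kin, powers = c(101, 242),
                              time_grid = seq(0, 600, 5),
                              noise = noise_model(sd = 0.01, seed = 7))
discriminate_models(traces)
#> Photolysis model discrimination
#>   verdict: II

a <- subset(traces, species == "A" & power_mw_cm2 == 101)
d <- subset(traces, species == "D" & power_mw_cm2 == 101)
jf <- fit_model_II_joint(mrm_trace(a$time_s, a$intensity, "A", 101),
                         mrm_trace(d$time_s, d$intensity, "D", 101))
fit_report(jf)
#>   parameter        estimate         sd unit
#> 1 lambda_A        0.0234     0.0000648 "1/s"
#> ...
#> 6 branching_ratio 0.925      0.00881   ""
```

The single-exponential fit of D is rejected (no model IV), the
normalized D profiles collapse across powers (no model III), and the
branching ratio 0.925 ± 0.009 < 1 says a direct A→C route exists but is
minor (model II, not I): ~92% of the photolyzed diazirine passes
through the selective diazo intermediate.

Fitting the five channel weights to a noisy synthetic yield curve of a
polar (Ser-like) target:

```r
pre <- reactivity_preset("diazo-dominant")
cur <- simulate_yield_curves("diazo-dominant",
         data.frame(power_mw_cm2 = c(5, 10, 20, 35, 50, 75, 100, 140,
                                     180, 220, 260, 300), time_s = 60),
         noise_model(sd = 0.01, seed = 11))
fit_weights(cur, pre$kin, pre$ch)
#> Elementary weights: b = (0.000, 0.762, 0.193, 0.000), c = 0.045
#>   mechanism score (b1+b2+b3+b4-c) = +0.909, R^2 = 0.9998
```

A score of +0.91 (generator: +0.90) classifies the target as
diazo-mediated — the carbene channel carries under 5% of the yield.

## Analysis workflow

The `analysis/` directory holds the narrative drivers, each a thin
script over the package functions, writing tables under `results/`:

1. `01_photolysis_models.R` — reactor arithmetic (0.196 mL tube,
   58.9 s residence, ~30 µM/s photons at 10 mW/cm²) and the four model
   curves.
2. `02_kinetic_fits.R` — per-power rate fits, power regression,
   branching ratio, model discrimination on synthetic traces.
3. `03_residue_reactivity.R` — channel profiles, weight fits and
   classification, yield surface over (t, [hv]), water quenching.
4. `04_distance_mapping.R` — toy-structure cross-link simulation,
   distance mapping, enrichment, SASA, mass-error comparison.

Run them in order with `Rscript analysis/01_photolysis_models.R` etc.

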