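# spovmclust

Statistical-mechanical modeling of membrane adsorption and clustering of
SpoVM, the curvature-sensing sporulation protein of *Bacillus subtilis*.

SpoVM, a 4 nm amphipathic helix, localizes to the convex outer forespore
membrane in vivo, and its in-vitro adsorption to spherical vesicles depends
strongly on vesicle radius over 0.75–30 µm. A single helix cannot read
micron-scale curvature (a 4 nm rod tangent to a 0.5 µm-radius sphere ends
only 0.16 Å off the surface), so curvature sensitivity must be collective.
This package is for membrane biophysicists who want to work with the
equilibrium cluster model of that collective sensing: compute its
adsorption isotherms and cluster-size distributions, fit competing
radius-dependent repulsion laws to adsorption data, and explore the
giant-cluster localization mechanism.

## The model

Membrane-bound proteins form clusters under short-range attraction
(ϵ_nn per bond) and longer-range pairwise repulsion (e_r per pair), all in
k_B·T units. In the dilute limit the normalised bound concentration is the
cluster sum

    C_v = Σ_{k≥1} k · exp(−k(k−1) e_r / 2) · C_s^k ,

with C_s the normalised bath concentration. Large C_s is dominated by
clusters of size k* ≈ ln(C_s)/e_r with ln C_v ≈ (ln C_s)²/(2 e_r). The
radius dependence of adsorption enters through e_r:

* curvature law `e_r = c1 − c2/r` — vanishes at r = c2/c1, below which
  adsorption diverges (the implausibility diagnostic for curvature
  sensing in vitro);
* tension law `e_r = c1 + c2·r` — tension of a pressurised vesicle scales
  with radius, giving the exp(−b·r) adsorption decay that matches the
  in-vitro behaviour.

A finite-range ("step") repulsion variant grows only linearly in cluster
size beyond a cutoff `k_max`, producing a condensation transition into one
giant cluster that amplifies a 1–2% binding-energy difference between two
membrane regions into near-total localization — the proposed in-vivo
curvature-sensing mechanism. An independent free-energy minimizer (exact
combinatorial entropy, quasi-Newton + scalar root polish) verifies the
dilute-limit closed forms. A seeded synthetic-data generator emulates the
(non-deposited) vesicle adsorption experiments so the fitting machinery is
testable end to end; see `vignettes/clustering-model.Rmd` for the science
and the numerical choices.

## Worked example

Simulate a radius profile under the tension law, then let both laws
compete for it:

```r
library(spovmclust)

tens <- repulsion_law("tension", c1 = 0.7, c2 = 0.61)
spec <- generator_spec(law = tens, A = 2, concentrations = 1,
                       noise_cv = 0.05, seed = 42)
d <- generate_dataset(spec)
head(d, 3)
#>   radius_um concentration adsorption     sigma   label
#> 1      0.75             1   3.691368 0.1725561 tension
#> 2      1.00             1   3.107268 0.1600125 tension
#> 3      1.75             1   2.759370 0.1356555 tension

compare_models(d, Cs = 1, seed = 42)
#> Model comparison (weighted SSR):
#>   tension   3.27717
#>   curvature 5.48454
#>   curvature-law divergence radius: 0.3389 um
```

The generating (tension) law attains the lower weighted SSR, and the
recovered coefficients sit near the generating values (c1 = 0.64,
c2 = 0.69, A = 2.07 for truth 0.7 / 0.61 / 2 at 5% noise). With the
reference wild-type *curvature*-law coefficients instead, the repulsion
crosses zero at

```r
divergence_radius(repulsion_law("curvature", c1 = 2.67, c2 = 1.1649))
#> [1] 0.4362921
```

0.44 µm — just below the smallest measured vesicles, which is why the
curvature law is rejected even where its fit looks adequate. Isotherm
values and cluster statistics come straight from the series:

```r
adsorption(1, 2)                    # 1.278131
mean_cluster_size(1, 2)             # 1.123316
```

and the two-region mechanism turns a 2% binding advantage (delta_b = 0.02)
from a 50.5:49.5 split at low concentration into essentially complete
localization in the giant-cluster regime:

```r
sys <- two_region_system(delta_b = 0.02, e_r0 = 0.2, k_max = 10,
                         K_cap = 1000)
localization_fraction(1e-6, sys)    # 0.505
localization_fraction(3, sys)       # ~1
```

A small CLI wraps the same functions
(`Rscript inst/scripts/spovm-tool.R isotherm --er 2 --cs 1`).

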