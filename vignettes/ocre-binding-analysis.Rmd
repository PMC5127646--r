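---
title: "Quantifying OCRE domain / proline-rich motif interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying OCRE domain / proline-rich motif interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocrebind)
```

## The system and the measurements

The OCRE (OCtamer REpeat) domain of the splicing regulator RBM5 is a small
twisted beta-sheet that exposes an array of tyrosine side chains on one
face. That surface reads out short proline-rich motifs (PRMs) in the
intrinsically disordered C-terminal tails of the Sm proteins SmN/B/B' —
runs of three or four prolines in a polyproline-II (PPII) conformation,
flanked by arginines, summarized by the consensus RPPP(P)G&phi;R with
&phi; a hydrophobic residue (Ile/Met/Val). Because single motifs bind
weakly (tens to hundreds of micromolar) the interaction is characterized
by solution methods that resolve weak, fast-exchanging complexes:

* **NMR chemical-shift perturbation (CSP) mapping.** Amide resonances of
  the labelled domain move continuously as unlabelled peptide is titrated
  in; the perturbation pattern maps the binding surface and its magnitude
  tracks occupancy.
* **Isothermal titration calorimetry (ITC).** Injection heats of the
  peptide-into-protein titration are fit with a one-site model to obtain
  the dissociation constant.
* **Structure-ensemble geometry.** NMR ensembles of the free and
  peptide-bound domain are compared by backbone RMSD, and the bound
  peptide's backbone dihedrals are classified against PPII geometry.

`ocrebind` implements each of these quantitative layers together with
seeded synthetic-data generators that produce every input type with known
ground truth, so the estimators can be validated end to end by parameter
recovery.

## Chemical-shift perturbations and the variant score

The combined CSP collapses the proton and nitrogen components of an amide
shift change into one scalar,

$$\Delta\delta = \sqrt{(10\,\Delta\delta_{HN})^2 + (\Delta\delta_N)^2},$$

with the proton change up-weighted by a factor of 10. This weighting is
equivalent, up to a global factor of ten, to the common
$\sqrt{\Delta\delta_H^2 + (\Delta\delta_N/10)^2}$ convention; we implement
the form above verbatim and expose the weight as the `weight_H` argument
(default 10) so either convention can be reproduced. Peaks are matched
across titration points by author residue number only — assignments are
assumed known, so no minimum-distance peak tracking is attempted — and a
residue observed in only one of the two points is reported as missing
rather than silently treated as an unperturbed zero.

Relative affinities of peptide variants are compared with a normalized
score: the combined CSPs of seven reporter residues on the binding surface
(Tyr470, Tyr471, Tyr479, Asp481, Asn483, Ser490, Tyr495 — the amides most
strongly perturbed by peptide binding) are summed at a fixed 1:10
protein:peptide ratio and divided by the wild-type sum:

```{r csp-score}
wt <- csp_profile(gen_titration(kd = 41, seed = 1))
weaker <- csp_profile(gen_titration(kd = 400, seed = 1))
csp_score(wt, weaker)
```

The score of the wild type against itself is exactly 1 by construction,
and the score is invariant to rescaling both profiles by a common factor.
Because the per-residue measure is not stated independently of the
combined-CSP definition, the package uses the combined formula for the
seven summed amides; this is a documented package choice. The score is a
semi-quantitative ranking device: at a fixed sub-saturating ratio it is
monotone in occupancy, but it is not an estimator of $K_D$.

Binding-surface mapping uses a configurable significance rule, by default
mean + 1 SD over the profile with a strict inequality (so a uniform
profile flags nothing); this rule is a package default for surface
display, not an experimental claim.

## The 1:1 binding quadratic and fast-exchange titrations

All fits rest on the exact ligand-depletion solution of 1:1 binding. With
total protein $P$, total ligand $L$ and dissociation constant $K_D$,

$$[PL] = \tfrac{1}{2}\left(P + L + K_D - \sqrt{(P + L + K_D)^2 - 4PL}\right),$$

evaluated internally in the cancellation-safe form
$2PL/(b + \sqrt{b^2 - 4PL})$ with $b = P + L + K_D$, and clamped to
$[0, 1]$ after division by $P$. In the fast-exchange regime the observed
combined CSP of residue $r$ at titration point $i$ is

$$\Delta\delta_{r,i} = \Delta\delta_{max}(r)\, f_{bound}(P_i, L_i, K_D).$$

`fit_titration()` fits one global $K_D$ shared across residues plus one
$\Delta\delta_{max}$ per residue. Since the model is linear in the
$\Delta\delta_{max}$ given $K_D$, they are profiled out analytically and
the optimization reduces to one dimension: the profile sum of squares is
scanned over a deterministic 241-point grid in $\log_{10} K_D$ (default
range $10^{-2}$–$10^6$ µM) and polished by golden-section search, after
which a Levenberg–Marquardt pass at the optimum supplies standard errors.
The grid-plus-polish strategy makes the fit start-point-free and exactly
reproducible. Flat trajectories (all $\Delta\delta_{max} \approx 0$) or an
optimum at the grid edge are flagged `converged = FALSE` rather than
returning a silent default.

```{r titration}
series <- gen_titration(kd = 41, protein_conc = 200,
                        ratios = c(0, 0.5, 1, 2, 4, 6, 8, 10), seed = 1)
fit_titration(series)
```

## One-site ITC: model, units and optimization

The simulator and the fitting model are the same function evaluated from
opposite directions. Concentrations follow the standard
perfusion-displacement rule for an overfilled fixed-volume cell — each
injection expels its own volume, so after a cumulative injected volume
$v$:

$$P = P_0\,\frac{1 - v/2V_0}{1 + v/2V_0}, \qquad
  L = L_{syr}\,\frac{v/V_0}{1 + v/2V_0}.$$

This matches the instrument class emulated here (small-volume perfusion
calorimeters; the active cell volume defaults to 200 µl). The cumulative
heat content after injection $i$ is $Q_i = \Delta H\, V_0\, n P_i\,
f_{bound}(nP_i, L_i, K_D)$ and the observed heat of injection $i$ is

$$q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2} + q_{dil},$$

where the middle term returns the heat carried out with the displaced
volume and $q_{dil}$ is an optional constant heat-of-dilution offset
(default 0, optionally fit — dilution controls are measured in practice
but their values are instrument-specific). Units are fixed package-wide:
concentrations in µM, volumes in µl, heats in µcal, enthalpies in
kcal/mol, with the single conversion constant
$1\ \mathrm{kcal\,mol^{-1}} \times 1\ \mu M \times 1\ \mu l =
10^{-3}\ \mu cal$ defined in one place.

`fit_itc()` minimizes the squared heat residuals with multi-start
Levenberg–Marquardt over a deterministic grid of log-spaced $K_D$ starts
($10^0$–$10^4$ µM in half-decade steps), which removes start-point
sensitivity while keeping noiseless fits bit-reproducible. $K_D$ (and n,
when free) are parameterized on the log scale; standard errors are mapped
back by the delta method. Two regime decisions matter for weak binders:

* **The pre-injection is excluded.** The small first injection (0.4 µl in
  the default schedule) is corrupted by syringe-tip diffusion during
  equilibration and is left out of the residuals by default.
* **n is fixed at 1 by default.** Most of these titrations are low-c
  (`itc_c_value()` gives $c = nP_0/K_D < 1$ for $K_D \gtrsim 100$ µM at
  100 µM cell protein), where stoichiometry and enthalpy are nearly
  confounded; fixing n is the standard remedy, and a warning fires if n
  is left free in a low-c fit.

```{r itc}
sim <- simulate_itc(kd = 41, dh = -10, n = 1,
                    design = itc_experiment(100, 1000))
fit_itc(sim)
```

For constructs carrying several equivalent motifs,
`apparent_kd_multivalent()` provides the first-order statistical-factor
avidity model $K_{D,app} = K_D/n_{motifs}$. The functional form of avidity
is not experimentally constrained here; this helper is a documented
modeling choice for ranking, not a fitted result.

## Motif scanning

`scan_strict()` matches the consensus `R P{3,4} G [IMV] R` left to right,
non-overlapping, with the longest admissible proline run taken at each
anchor; this mirrors how tandem motifs in the Sm tails are counted.
`scan_relaxed()` instead finds maximal proline runs of admissible length
and requires an arginine within ±3 residues on either side (both window
and both requirement toggles configurable; the preceding arginine
contributes more to binding, so `require_post_arg = FALSE` is the common
relaxation). Runs longer than four prolines never match strictly; in
relaxed mode they are reported with a warning by default or dropped on
request. &phi; defaults to {I, M, V}; Leu/Phe are chemically plausible
but untested, so they are admissible only by explicit configuration.
Coordinates are 1-based inclusive in all reports; `write_hits_bed()`
converts to BED's 0-based half-open convention.

```{r motif}
scan_strict("GMRPPPPGIRG")
```

## Structure geometry

Backbone dihedrals follow the IUPAC definitions, computed with circular
arithmetic (degrees at the interface, vectors internally); a residue is
classified PPII when both $\phi$ and $\psi$ lie within a circular
tolerance (default 30°) of the canonical $\phi = -75°$, $\psi = +145°$.
Superposition is the closed-form Kabsch solution with the SVD reflection
correction, so only proper rotations are returned; collinear selections
are rejected as degenerate. Ensemble precision is the mean ± SD of
superposed RMSD over all unordered model pairs. The backbone atom set is
{N, CA, C'} (O excluded), the common convention for NMR-ensemble
precision; because published RMSDs rarely state their convention, every
RMSD result carries a `convention` record naming the chain, residue
range, atom set and representative rule used. Free-versus-bound
comparisons use model 1 of each ensemble by default, with a medoid rule
(minimal summed RMSD to ensemble mates) as the alternative.

```{r geometry}
pp <- gen_ppii_coordinates(6)
classify_ppii(backbone_dihedrals(pp))
ens <- gen_jittered_ensemble(pp, n_models = 10, jitter_sd = 0.3, seed = 1)
ensemble_pairwise_rmsd(ens)
```

## What the synthetic generators emulate — and what they do not

Every generator is deterministic under a fixed seed, restores the
caller's RNG state, and returns its ground truth alongside the artifact
so recovery tests never re-derive it.

* `gen_titration()` emulates HSQC titrations of a 200 µM labelled domain
  against a ligand ladder up to 10-fold excess (default 8 points), with
  per-residue maximal shifts between 0.3 and 1.0 ppm on the combined
  scale — typical magnitudes for a direct peptide-binding surface. The
  split of each combined shift into ¹H and ¹⁵N components is a
  seed-fixed random direction per residue, recorded in the truth, since
  only combined values are observable targets. Gaussian read noise is
  added per shift component. Not emulated: peak overlap, line broadening
  from intermediate exchange, or assignment errors.
* `gen_itc()` produces one-site perfusion thermograms on the reference
  schedule (0.4 µl + 38 × 1 µl) with optional Gaussian heat noise. Not
  emulated: baseline drift, injection-peak integration error, or active
  heats of dilution beyond a constant offset.
* `gen_sequences()` plants strict-consensus motifs into backgrounds drawn
  uniformly from the alphabet excluding P and R, with ≥ 5-residue
  spacers, which guarantees that planted and detected motif counts agree
  under both scan modes. Real disordered tails are compositionally
  biased (RG-rich) in ways the uniform background does not reproduce.
* `gen_helix_coordinates()` builds N–CA–C' backbones with ideal
  Engh–Huber bond geometry and uniform torsions by natural-extension
  placement, so the dihedral reader recovers the set angles to numerical
  precision; `gen_ppii_coordinates()` fixes $\phi = -75°$, $\psi = +145°$,
  $\omega = 180°$. Side chains, carbonyl oxygens and thermal disorder are
  not modelled.

Passing recovery tests on these inputs demonstrates that the estimators
are correct implementations of their models; it does not demonstrate
robustness to the instrumental artifacts listed above, which real data
contain.

## Problem sizes and numerical choices

The validation suite runs at desk scale: titration fits use 8-point
ladders with 7 residues; ITC fits use the 39-injection reference
schedule; noise studies use 50 seeded replicates at 2% Gaussian noise
(median recovered $K_D$ within 10% of truth); ensemble statistics use
≤ 10-model toys where brute-force pair loops and an Euler-angle search
provide independent oracles. Noiseless round trips are required to
recover generator parameters to 0.1% relative error. Residue numbering is
1-based author numbering throughout (the OCRE domain spans residues
451–511; expression-tag residues are excluded from all default residue
sets). Ties and degenerate inputs fail loudly: empty residue
intersections, zero wild-type CSP sums, all-zero heats and collinear
atom selections all raise or flag rather than return defaults.

## Known limitations

* Only the 1:1 one-site model is implemented; sequential or cooperative
  multi-site ITC models and exchange-regime lineshape analysis are out of
  scope.
* The avidity helper is a statistical-factor approximation; it ignores
  effective-concentration physics of linker length.
* The CSP score inherits the assumptions of fast exchange and a shared
  binding mode across variants; slow- or intermediate-exchange variants
  would need lineshape treatment.
* RMSD benchmarks against deposited NMR ensembles depend on unstated
  conventions (residue range, representative model, refinement); the
  package therefore reports its convention with every number rather than
  asserting a unique reproduction.
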