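---
title: "A whole-body PBPK model of intravenous bacteriophage: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A whole-body PBPK model of intravenous bacteriophage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagepbpk)
```

## The problem

Bacteriophage therapy needs the same quantitative dose-to-exposure link
that small-molecule antibiotics have, but phage are ~60-400 nm virions:
their disposition is governed by vascular permeability, uptake by
tissue-resident phagocytes (the mononuclear phagocyte system, MPS), and
cell-mediated clearance at epithelial surfaces, not by metabolism or
glomerular filtration of small solutes. `phagepbpk` implements a
whole-body physiologically based pharmacokinetic (PBPK) model of
intravenously administered, radiolabeled phage in the uninfected host
(no bacterial amplification), together with the workflows that turn it
into an analysis pipeline: naive pooled maximum-likelihood estimation on
biodistribution data, empirical-Bayes covariate screening, local and
global sensitivity analysis, interspecies scaling with clinical-trial
simulation, and a study-faithful synthetic data generator.

## Model structure

Every organ is a permeability-limited tissue with a vascular and an
interstitial space. For tissue $i$ with blood flow $Q_i$, vascular volume
$V_{i,v}$ and interstitial volume $V_{i,int}$:

$$V_{i,v}\frac{dC_{i,v}}{dt} = Q_i\,(C_a - C_{i,v})
  - P\,Q_i\left(C_{i,v} - \frac{C_{i,int}}{K_p}\right)$$

$$V_{i,int}\frac{dC_{i,int}}{dt} = P\,Q_i\left(C_{i,v} -
  \frac{C_{i,int}}{K_p}\right) - k_{up}(t)\,C_{i,int}V_{i,int}
  + k_{rel}\,A_{i,MPS}$$

The permeability coefficient $P$ is shared across the body; the partition
coefficient takes one of three values (lung/kidney; liver/spleen/stomach;
rest of body). The lung sits in series and receives the whole cardiac
output; all other organs are perfused in parallel from arterial blood,
and the liver receives dual input from its hepatic artery and the portal
venous outflow of stomach, spleen and intestines.

MPS uptake is saturable and capacity-limited:

$$\frac{dA_{i,MPS}}{dt} = k_{up}(t)\,C_{i,int}V_{i,int}
  - (k_{rel} + k_{deg})\,A_{i,MPS}, \qquad
  k_{up}(t) = k_{up,max}\left(1 - \frac{A_{i,MPS}}{A_{i,max}}\right)$$

with $A_{i,max} = M_i V_i\,10^{A^*}/10^5$ phage per tissue, where $M_i$
is the tissue phagocyte density (cells/g) and $10^{A^*}$ the per-1e5-cell
capacity in PFU. Expressed in %ID the capacity is divided by the
administered dose in PFU — this is what makes the system nonlinear in
dose. $k_{rel}$ is tied to $k_{up,max} = \ln 2 / T_{up}$ for
identifiability, and $T_{up}$ is fixed at 0.001 h (uptake is much faster
than endosomal degradation).

First-order active clearance at epithelial surface sites, a single
estimated parameter in L/h/kg, totals $CL_{active} \times BW$. It is
split between a urinary route (kidney, draining into a urine compartment
with transit half-life $T_{U,out}$) and a gastric route (liver, stomach,
small and large intestine, draining into a stomach-contents pool with
transit half-life $T_{Sto,out}$) in proportion to those organs'
interstitial volumes, which serve as a surface-area proxy.

A twin model tracks free radiolabel: slow thermal deconjugation
(2.98e-4 h⁻¹) in every labeled-phage compartment, fast liberation by MPS
degradation, release from the phagocyte pool to blood at 0.05 h⁻¹,
first-order elimination with a 7 h half-life and thyroid uptake with a
30 h biological half-life — all fixed from published iodide kinetics.
Tissue observables are total label (phage in all three spaces plus
MPS-resident free label plus the tissue's share of circulating free
label, distributed with unit partition) per gram of organ.

## Design choices made where the design was open

Several structural points are not determined by the equations alone; the
package resolves them as follows, and each is revisitable through
configuration rather than code edits.

**Where the active clearance samples.** Applying surface-site clearance
to the interstitial concentration starves the gastric route: with the
liver/spleen/stomach partition coefficient of ~2e-4, those interstitia
are nearly empty, the stomach lumen receives ~2 %ID instead of the
double-digit amounts the process must explain, and the blood terminal
half-life stretches to ~30 h. The surface sites (glomerular/tubular
epithelium, hepatobiliary and gastric interfaces) face the perfusing
blood, so the clearance acts on the organ's vascular-space
concentration. With this form the simulated blood terminal half-life is
~9.8 h and the stomach pool fills to ~9 %ID over 1-4 h.

**Where the MPS samples.** The canonical balance above feeds the MPS
from the interstitium. At the fitted GI partition coefficient this
leaves the liver and spleen MPS nearly idle — which is exactly what the
model's own global sensitivity analysis implies (blood exposure almost
entirely attributed to the active clearance, with capacity, uptake and
degradation parameters near zero). The alternative — intravascular
(sinusoidal) uptake by Kupffer cells and red-pulp macrophages, available
via the `mps_vascular` argument — produces the long spleen/liver
residence times that moment analysis of biodistribution data shows, but
is incompatible with that sensitivity pattern. The two printed outcomes
cannot both follow from one structure; the package defaults to the
literal equations and documents the tension rather than hiding it.

**Clearance allocation and GI anatomy.** One parameter covers both
excretion routes; the split (by interstitial volume) and the choice to
pool all gastric-route output into the single measured stomach-contents
compartment reflect what the data can identify — finer GI luminal
anatomy is unidentifiable from stomach-contents measurements alone.

**Free-label disposition.** Anything richer than a well-mixed blood pool
with fixed elimination and thyroid uptake is unidentifiable; free label
is attributed to tissues with unit partition for observables.

## Parameters

`phage_parameters()` carries the canonical estimates: partition
coefficients 0.395 (lung/kidney), 2.12e-4 (liver/spleen/stomach), 0.934
(rest); permeability 0.0427; MPS capacity 10^3.81 PFU per 1e5 phagocytes
(fixed); uptake half-life 0.001 h (fixed); degradation half-life
0.0437 h; active clearance 0.0129 L/h/kg with a strain covariate of
exp(-1.94) for the reduced-clearance strain; gastric and urine transit
half-lives 3.28 h and 1.73 h; and per-tissue additive residual SDs.
Running text elsewhere quotes a slightly different triple (permeability
0.0227, clearance 0.0145 L/h/kg, degradation 0.0301 h);
`phage_parameters(alternative = TRUE)` loads that variant. The covariate
is applied as a log-scale effect, `CL * exp(theta)`; the quoted
"10.7-fold" reduction and the quoted absolute covariate-adjusted value
are not mutually consistent with exp(-1.94) = 1/6.96, and the package
uses the exponential form throughout.

Physiology (organ weight and flow fractions, vascular/interstitial
sub-volumes, phagocyte densities, allometric cardiac output
16.5·BW^0.75 L/h) ships as editable YAML per species, compiled from
standard mouse/rat reference tables and ICRP-style human values, with
phagocyte densities from literature macrophage counts (Kupffer cells
~1.5e7/g, spleen ~5e7/g in mouse; adjusted per species). These tables
are the model's largest source of uncertainty: none of the downstream
quantities that depend on organ-level anatomy should be read tighter
than a few tens of percent. Exact values can be dropped in by pointing
`get_physiology(config = ...)` at a replacement file.

The dose in PFU enters only through the MPS capacity normalization. The
mouse biodistribution design is emulated at a nominal 1e10 PFU per
animal (50 µL of a ~2e11 PFU/mL stock); at that dose every tissue's MPS
is saturated within seconds and MPS throughput is capacity-limited.

## Numerical choices

The coupled system (61 states for the 13-organ mouse) is integrated with
`lsoda` through a compiled right-hand side, relative tolerance 1e-8 and
absolute tolerance 1e-10. Uptake at $\ln 2 / 0.001\,h \approx 693$ h⁻¹
makes the system stiff; a non-stiff integrator is not an option. Boluses
are initial-condition increments at each administration time; a "rapid
5-min push" is a 0.0833 h zero-order infusion; multi-dose schedules are
integrated piecewise with no superposition (the MPS saturation makes
superposition invalid). Mass balance — administered label equals the sum
of all compartments and cumulative sinks — holds to ~1e-11 %ID and is
asserted at 0.1 %ID in the tests. A pure-R twin of the right-hand side
(`tissue_derivatives`) is tested against the compiled code on random
states, and the linear limit of the solver is verified against an
eigen-decomposition oracle to 0.5%.

Moment metrics (AUC, AUMC, mean residence time) use the linear trapezoid
on a 0.01 h grid over 0-24 h; terminal half-life is log-linear least
squares over the last points (default 3; 5 late samples for the blood
curve). Both plain and log10-scale relative bias/RMSE are provided
because the two conventions disagree in the literature this package
serves (a reported |rBias| exceeding the paired rRMSE is impossible
under the plain definitions).

## Estimation

The pooled fit is direct maximum likelihood — with no random effects,
stochastic EM reduces to ML, so the package optimizes the exact
objective rather than re-implementing a licensed algorithm. Free
structural parameters are optimized on the log scale (`nlminb`,
multi-start with log-uniform ±3-fold jitter, 5 starts by default);
residual sigmas are profiled analytically. RSEs come from the observed
information matrix by central finite differences (step 1e-4 on the log
scale). The covariate screen computes per-animal MAP estimates under a
log-normal prior (ω = 1) centered at the pooled estimates, then ranks
|correlation| of the individual estimates against phage size (Spearman)
and strain indicators (point-biserial), flagging |r| > 0.3; candidates
enter likelihood-ratio testing (α = 0.05) in descending order. Animals
with fewer than two observations (the early-blood microsample groups)
are excluded from the screen.

On synthetic three-strain data at the default design, the fit recovers
the permeability and active clearance within ~10-20% (well inside the
30% acceptance band), estimates their RSEs near the reported 14.3% and
5.1%, and the screen + LRT detect the planted strain covariate in every
seeded replicate tested.

## Sensitivity analysis

Local: each parameter is moved fivefold up and down (the capacity in
PFU space) and the normalized change of blood AUC,
$(AUC_{test}-AUC_{ref})/AUC_{ref}$, is reported at 12, 24 and 48 h.
Global: 2,000 joint draws, each parameter uniform on $[\theta/5,
5\theta]$ — the capacity log-uniformly over the same fivefold limits,
since sampling its log10 *value* uniformly over $[3.81/5, 5 \times
3.81]$ would span capacities up to 10^19 PFU and make the capacity
dominate every index, contradicting the analysis it reproduces. Output
is blood AUC over 24 h after a single mouse bolus (horizon
configurable). First-order indices use the rank-permutation estimator
(sort by input, correlate consecutive outputs), which needs no extra
model runs; bias and CIs come from half-sample subsampling without
replacement, because a with-replacement bootstrap creates rank ties that
inflate rank-based estimators. The estimator is validated against the
closed-form indices of an additive model to 0.05 at n = 2000.

In this reconstruction the active clearance is by far the most
influential parameter (first-order index ~0.65 at the 24 h horizon),
with the rest-of-body partition coefficient a distant second (~0.1-0.2)
— a truncated-horizon AUC necessarily gives distribution volume a real
variance share, since total exposure $Dose/CL$ is volume-independent
only at infinite horizon.

## Interspecies scaling and trial simulation

System parameters carry over; anatomy, flows and phagocyte densities
come from the target species table; active clearance is allometric in
body mass with exponent 1 by default (its units are per kg; 0.75 is
available). Human simulations assume 5 L blood, plasma-equivalent
reporting, no red-cell partitioning, and IV administrations as rapid
5-min pushes. Daily doses of 1e7-1e12 PFU across single, Q24H, Q12H and
continuous schedules are integrated through the full nonlinear system;
Monte Carlo replicates draw parameters log-normally with CV = RSE/100
and report 5th/50th/95th percentile bands. At these clinical doses the
MPS is even deeper into saturation than in the mouse, so dose-normalized
exposure rises gently with dose, single doses fall below the 100 PFU/mL
plaque-assay quantification limit by 12 h across the lower ladder, and
continuous infusion reaches 95% of its plateau in ~2.3 h.

## The synthetic-data generator

`generate_study()` emulates the destructive mouse design: three strains
(63, 227 and 400 nm), six terminal groups of five animals per strain
(0.5-24 h, or 0.5-72 h for the intermediate strain), each animal
contributing all twelve measured quantities (nine organs, blood, stomach
contents, urine) at its single euthanasia time, plus four separate
early-blood groups (1, 5, 15, 30 min) of five animals contributing one
blood value each — 380 records per strain. Noise is additive Gaussian
per tissue with the fitted sigmas, floored at zero; covariate effects
are planted as strain-specific clearance multipliers. Per-animal body
masses (22-30 g) are recorded as metadata while the generative
simulation runs at the nominal 26 g, matching the pooled-analysis
assumption. The generator reproduces the study's *design*, not its data:
real biodistribution data add inter-animal physiology variation,
counting statistics and dissection variability that the additive error
model only summarizes, so passing recovery tests here demonstrates
estimator correctness, not field performance.

## Known limitations

- Organ fractions and phagocyte densities are reference-compilation
  defaults, not the study's own anatomical table; organ-level moment
  metrics inherit that uncertainty.
- The tension between the residence-time ordering and the sensitivity
  pattern (see *Where the MPS samples*) is structural and left visible.
- The stomach-contents pool fills to ~9 %ID over 1-4 h against reported
  double-digit observations; with the estimated clearance the gastric
  flux is bounded by clearance x blood concentration (~5 %ID/h), so
  substantially larger luminal amounts require a mechanism (e.g. active
  iodide secretion by gastric mucosa) outside this model.
- No phage replication or pharmacodynamic coupling; no oral/inhaled
  routes; no bladder recirculation; no disease-state physiology.
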