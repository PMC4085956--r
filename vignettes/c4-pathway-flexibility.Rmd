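---
title: "Compartmental kinetics of mixed C4 photosynthetic pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental kinetics of mixed C4 photosynthetic pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4flex)
```

## The model

C4 leaves concentrate CO2 around Rubisco by fixing bicarbonate with PEP
carboxylase (PEPC) in the mesophyll cells (MC), shuttling the resulting
C4 acids into the bundle sheath cells (BSC), and decarboxylating them
there. `c4flex` resolves this physiology into a compartmental kinetic
model: metabolite pools live in the MC cytosol, the BSC cytosol and the
BSC chloroplast, with the two chloroplasts holding the ATP/ADP and
NADPH/NADP+ pools; every enzymatic or transport step is a rate law on
those pools; and each metabolite obeys a balance equation

$$\frac{dM}{dt} = v_{in} - v_{out},$$

integrated with a stiff solver until the right-hand side vanishes. All
reported quantities — net assimilation $A = v_c - 0.5\,v_o - R_d$,
leakiness $\phi$ (CO2 leak flux over PEPC flux), photorespiration
$0.5\,v_o$, metabolite gradients and pools — are read off the converged
steady state.

Five pathway variants share one reaction network and differ only in
which enzymes (and the transport steps only they feed) are active:

| variant | transfer C4 acids | C3 return | decarboxylase(s) |
|---|---|---|---|
| `nadp_me` | malate | pyruvate | NADP-ME |
| `asp_mal_me` | malate + aspartate | pyruvate + alanine | NADP-ME (via BSC MDH) |
| `asp_mal_pepck` | malate + aspartate | pyruvate + alanine + PEP | NADP-ME + PEPCK |
| `asp_mal_pepck_me` | malate + aspartate | pyruvate + alanine + PEP | NADP-ME + PEPCK |
| `asp_pepck_only` | aspartate | alanine + PEP (pyruvate returns) | PEPCK |

Enzyme capacities are the measured/assumed maximum activities of
NADP-ME-type leaves (PEPC 170, NADP-ME 90, MDH 90/60, PPDK 90,
aminotransferases 400, Rubisco 65, PEPCK 60 µmol m⁻² s⁻¹). NADP-ME
releases CO2 inside the BSC chloroplast; PEPCK releases it in the BSC
cytosol and pays one ATP per turnover from the sheath's supply. CO2 and
O2 keep an explicit cytosol/chloroplast split with an envelope
conductance, so the two release sites face different diffusion paths to
Rubisco and to the leak — this is what makes PEPCK-heavy pathways
leakier.

## Light reactions and the energy budget

Whole-chain electron transport follows the non-rectangular hyperbola
$\theta J^2 - (I_2 + J_{max})J + I_2 J_{max} = 0$, per cell type. The
mesophyll runs linear electron transport (LET) only; the bundle sheath
splits light between LET and cyclic flow by the single fraction
$u = v = \mathrm{LET_{BSC}}$ applied to both the PSII light share and
$J_{max}$. LET yields NADPH, ATP and O2 (one NADPH, ~1.3 ATP and half an
O2 per two electrons); cyclic flow yields ATP only. ATP and NADPH
synthesis rates are capped at $\min(V_{maxE},\ \varepsilon J)$ of the
relevant chain; with $u = 0$ the sheath makes no NADPH and evolves no O2.

Two conventions matter and are deliberate:

* the PSII half-share of absorbed quanta applies to the linear chains,
  while cyclic flow is PSI-driven and uses the remaining sheath quanta in
  full;
* per photon, the sheath's LET and cyclic chains yield similar ATP
  (`eps_atp_b` ≈ 2 × `eps_atp_cyc`), so that re-partitioning sheath light
  between the two chains does not by itself change the ATP budget. This
  reproduces the observed insensitivity of the optimal light allocation
  to the assumed LET fraction.

The mesophyll ATP yield (`eps_atp` = 0.65 per electron, i.e. ~1.3 ATP
per 2 e⁻) is the chemiosmotic value; it makes mesophyll ATP mildly
co-limiting with NADPH, which is what penalises the extra PPDK turnover
of overcycling-prone mixed pathways at low light.

`jmax_m` and `jmax_b` were calibrated once so the standard variant's
light response saturates near the observed maize range
(A ≈ 35–40 µmol m⁻² s⁻¹ at PPFD 2000, Ci 150 µbar); the CO2 leak
conductance `g_co2` was set so standard-variant leakiness sits in the
0.2–0.3 band at intermediate light. Both are recorded in
`c4_params()` and were not revisited afterwards.

## Transport and the leak

Metabolite movement between the cytosols is diffusive,
$v = g\,(C_{MC} - C_{BSC})$, with one conductance `g_met` for all
transfer acids (malate, aspartate, alanine, pyruvate, PEP, PGA, triose
phosphate). CO2 and O2 leak between the BSC and MC cytosols with
conductances on the dissolved-concentration basis; because CO2 is ~25×
more soluble than O2, the equal concentration-basis conductances
correspond to a ~0.04 O2:CO2 ratio on the partial-pressure basis.
Leakiness is reported as leak flux over PEPC flux, the standard
overcycling measure.

## Assumptions the results hinge on

**Mesophyll share of PGA reduction.** The PGA/triose-phosphate shuttle
lets the mesophyll reduce part of the Calvin-cycle PGA with its own
NADPH and ATP. The model caps the mesophyll share at `pga_export_max`
(default 0.75) of instantaneous PGA production: the sheath's own
phosphate economy retains at least a quarter of the reduction flux. The
cap is what makes bundle-sheath NADPH an obligatory currency — and hence
what makes the aspartate-only/PEPCK-only pathway infeasible without
sheath PSII, since aspartate moves no reducing equivalents and PEPCK
generates none.

**Aspartate flux share.** The aspartate route is held at
`asp_flux_target` (default 25%) of C4-acid formation by capping
mesophyll AspAT at 1/3 of the instantaneous MDH flux, mirroring the
carbon-label partition between malate and aspartate. Without the cap the
aspartate loop expands opportunistically wherever sheath ATP is in
surplus, which erases the low-light superiority of the standard pathway.
The cap does not apply to the aspartate-only variant, where aspartate is
the sole carrier by construction.

**Directed aminotransferases.** AspAT and AlaAT are modelled as
irreversible Michaelis–Menten steps in the direction the cycle runs them
(MC aminates OAA and deaminates alanine; BSC the converse). With
near-equilibrium kinetics the aspartate route disengages at low light
and the mixed-pathway contrasts vanish; the directed forms keep the
calibrated share meaningful across the light range. MDH remains
reversible (Haldane-consistent convenience kinetics).

**Pool-sizing machinery.** The C4 carrier families (PEP/OAA/MAL/PYR and
the amino pool) are otherwise conserved cycles, so the network carries
the standard anaplerotic links that size them: a feedback-inhibited
PGA→PEP valve (phosphoglycerate mutase + enolase) with a slow return, a
pyruvate-kinase link into the pyruvate/alanine family with a slow
oxidative drain, feedback guards on PEPC by its C4-acid products, and
PGA/RuBP product feedbacks on Rubisco and RuBP regeneration that stand
in for stromal phosphate conservation. Each has a small flux at steady
state; collectively they make the steady state unique and independent of
the initial concentrations (this is tested).

## Numerical choices

* Stiff integration with `deSolve::lsoda` (rtol 1e-8, atol 1e-10 µM)
  over geometrically growing horizons; steady state is declared when
  max |dM/dt| / max(M, 1 µM) < 1e-8 s⁻¹ or every |dM/dt| < 1e-6 µM s⁻¹
  (the absolute branch absorbs the power-law tails of dark and
  carbon-starved states). Results carry `converged` and the residual.
* Concentrations are clipped at zero inside the rate evaluator so tiny
  negative integrator excursions cannot flip reaction directions.
* Scans solve every grid point from the same documented initial state
  (all metabolite pools 50 µM; Calvin intermediates 300 µM; glutamate
  2 mM; adenylates 1000/500, pyridines 250/250 µM) rather than chaining
  states across points: degenerate corners (a dark, carbon-drained leaf)
  are also stationary, and warm-starting can silently hand such a branch
  from one grid point to the next. Within the productive regime the
  steady state is initial-condition independent.
* Gases are stored as dissolved µM and reported in µbar/mbar via fixed
  Henry constants (25 °C).
* Crossovers on scan grids are reported as bracketing-interval midpoints
  with the half-width attached (PPFD step 50; allocation step 0.05).

## What the simulations do and do not show

The drivers are the study conditions throughout: Ci = 150 µbar, ambient
O2 210 mbar, Rd = 1 µmol m⁻² s⁻¹ split equally between the cell types;
light-response scans run PPFD 0–2500, allocation scans run at PPFD 300,
the PEPC sensitivity and gradient snapshots at PPFD 2000. Under these
conditions the model reproduces the characteristic behaviour of mixed
decarboxylation pathways: the standard NADP-ME configuration is the most
efficient at low light, the Asp+MAL/ME configuration overtakes it near
PPFD 1000, every PEPCK-containing configuration pays for cytosolic CO2
release with higher leakiness, and only pathways that deliver reducing
power to the sheath (via malate or sheath PSII) can assimilate at all.

Known limitations: there is no explicit cytosolic or organelle-position
diffusion resistance inside the bundle sheath, so leakiness of
cytosol-releasing (PEPCK) pathways is likely somewhat overestimated; the
supply of amino groups is a closed glutamate pool rather than nitrogen
metabolism; phosphate is not tracked explicitly (its conservation enters
only through the lumped product feedbacks); and one aminotransferase
ordering near the light-response crossover is knife-edge — at exactly
PPFD ≈ 1000 the mixed-ME variant's leakiness briefly dips below the
standard's while the assimilation ranking changes hands. Transients are
not analysed; every reported quantity is a steady state.
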