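---
title: "Constraint-based flux estimation, ensemble sampling and expression-based prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based flux estimation, ensemble sampling and expression-based prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limfba)
```

# The model

A metabolic network with reactions $1..n$ and flux vector
$x \in \mathbb{R}^n$ (mmol/min throughout) is analyzed under three kinds of
constraints:

$$E x = f, \qquad G x \ge h, \qquad A x = b + \epsilon .$$

The first rows of $E$ are the stoichiometric balances of the *internal*
metabolites with $f = 0$: at metabolic steady state, production equals
consumption for every species inside the model boundary. Boundary
metabolites — blood-side species, and intracellular cofactors whose
turnover is closed by processes outside the model — are excluded from the
balance. A flux known precisely (a measured uptake, a pathway flux fixed
as a fraction of another measurement) is imposed as an extra equality row.
$G$ contains one row per irreversible reaction ($h = 0$): irreversible
fluxes cannot run backwards. Reversible fluxes carry **no** bounds at all
unless fixed — the constraint system contains only the steady-state and
irreversibility information, not arbitrary box bounds, so any finite
optimum is forced by network structure rather than by bound artifacts. The
third block is used only by the ensemble sampler: $A$ selects the measured
fluxes, $b$ their values and $\epsilon$ their Gaussian measurement error
with standard deviations `sd`.

**FBA.** `solve_fba()` maximizes or minimizes a linear objective
$c^\top x$ over $\{E x = f,\ G x \ge h\}$ with a two-phase dense simplex
implemented in the package (no LP library is required). Solutions satisfy
the constraints to the feasibility tolerance $\varepsilon_{feas} = 10^{-9}$
(absolute). When the LP has alternate optima the solver deterministically
returns one vertex for a fixed input ordering; non-uniqueness is
quantified, never hidden, by `flux_variability()`, which re-solves two LPs
per reaction subject to retaining (a fraction of) the optimal objective.
A flux is considered uniquely determined when its range width is below
$10^{-6}$ mmol/min, three orders of magnitude below the reporting
precision of the input data.

# The brain fixture

`build_brain_model()` returns a core model of human brain energy
metabolism: 71 reactions over 89 metabolites spanning glycolysis, the
pentose phosphate pathway (PPP), the TCA cycle, the malate–aspartate
shuttle, the glycerol-3-phosphate shuttle, the glutamate/GABA shunt,
oxidative phosphorylation, and the associated transport steps, using
Recon-1-style identifiers (`R_HEX1`, `R_AKGMAL`, `M_glc_DASH_D_c`, ...)
and gene associations given as boolean AND/OR expressions over human gene
symbols. The reconstruction is a **synthetic transcription** curated for
this package from the standard biochemistry of these pathways; it is not a
copy of any database export. Choices a reader should know about:

* **Boundary species.** The seven blood-side species (glucose, lactate,
  pyruvate, O2, CO2, water, protons) are boundary metabolites, so the
  transport reactions act as exchange fluxes. The cytosolic NADP+/NADPH
  pair is also boundary: the model contains the oxidative PPP that
  produces NADPH but not the biosynthetic and antioxidant machinery that
  consumes it, so NADPH turnover is closed outside the model. A species
  is recognized as boundary on SBML import when `boundaryCondition` is
  set or its id ends in `_b` (the BiGG export convention); both rules can
  be adjusted in `read_sbml()`.
* **Proton bookkeeping.** Protons are balanced separately per compartment
  (`M_h_c`, `M_h_m`), which is what ties the respiratory chain to ATP
  synthase flux: complex I translocates 4 H+ per NADH, complex III 4 per
  ubiquinol, complex IV 4 per O2 (2 per electron pair), while ATP
  synthase consumes 4 cytosolic protons per ATP and the phosphate carrier
  one more. A plasma-membrane proton exchanger and a mitochondrial proton
  leak close the proton cycle.
* **Mitochondrial glutamate carrier.** The GABA shunt regenerates
  glutamate in the matrix (GABA transaminase) while glutamate
  decarboxylase is cytosolic, so a glutamate carrier links the two pools.
  It is modeled electroneutral at this level of granularity; with a
  proton-coupled variant the whole-brain ATP budget shifts by about 0.02
  mmol/min.
* **Calibration.** Reversibility assignments and the proton stoichiometry
  were fixed so that, under the packaged study constraints, the maximal
  net ATP budget reproduces the published whole-brain values (objective
  8.49, ATP synthase 7.48 mmol/min, both to ±0.01) and the optimum is
  unique under flux variability analysis. The fixture is therefore
  suitable as a regression anchor: `tests/testthat/test-acceptance.R`
  asserts these golden numbers.

`brain_study_data()` carries the measured whole-brain exchange rates
(median ± sd, mmol/min, for a 1.4 kg brain): glucose 0.284 ± 0.058,
lactate −0.013 ± 0.032, pyruvate −0.003 ± 0.004 (negative = release), and
the two pathway fractions: PPP flux = 6.9 % of glycolysis, GABA shunt =
32 % of glucose oxidation. `derive_fraction_constraints()` turns the
fractions into fixed fluxes for glucose-6-phosphate dehydrogenase and
glutamate decarboxylase, rounding to three decimals (0.020 and 0.091)
*before* they enter $E$/$f$ — the published analysis applied the printed
values, and reproducing its results requires doing the same.

```{r fba}
model <- build_brain_model()
lim <- build_lim(model, fixed_fluxes = brain_fixed_fluxes())
fit <- solve_fba(lim, brain_atp_objective())
fit
```

The objective is the net cytosolic ATP balance
`R_ATPS4m - R_NDPK1m - R_HEX1 - R_PFK - R_PGK + R_PYK`: synthase and
pyruvate kinase produce ATP; hexokinase and phosphofructokinase consume
it; phosphoglycerate kinase and the mitochondrial NDP kinase are written
in the ATP-consuming direction in Recon-style databases and therefore
carry negative fluxes (and negative objective signs) when producing ATP.

# Ensemble sampling of the flux polytope

Measurement error on the exchange fluxes propagates into every estimated
flux. `sample_ensemble()` quantifies this by sampling flux vectors with
density proportional to the likelihood

$$L(x) = \exp\Big(-\tfrac12 \sum_i \big((A x - b)_i / sd_i\big)^2\Big)$$

restricted to the constraint polytope. The implementation:

1. Parameterize the equality-feasible affine subspace as $x = x_0 + Z q$,
   with $Z$ an orthonormal basis of the null space of the stacked equality
   system obtained from the SVD (rank decisions at relative tolerance
   $10^{-10}$).
2. Rotate $Z$ onto the right singular vectors of the sd-scaled measurement
   map $\mathrm{diag}(sd)^{-1} A Z$. After this rotation the coordinates
   split into likelihood-informed directions and likelihood-flat
   directions, which is what lets the chain cross wide but flat regions
   of the polytope (e.g. the proton-leak direction of the brain model)
   quickly.
3. Propose Gaussian steps $q' = q + \sigma \odot \eta$,
   $\eta \sim N(0, I)$. The *jump* parameter (default 0.1) is *relative*:
   $\sigma_j$ is `jump` times a per-direction scale, defined as the
   feasible range along direction $j$ from the starting point, capped by
   the width the likelihood allows in that direction (six posterior
   standard deviations). This is the package's resolution of what a
   "relative proposal step size" is relative to.
4. Reflect proposals across violated inequality hyperplanes until
   feasible (the *mirror* move; reflections are isometries, so the
   proposal stays symmetric and the Metropolis ratio is just
   $L(x')/L(x)$). A proposal needing more than 1000 reflections — far
   above anything observed in practice — is rejected.
5. Accept/reject by Metropolis; keep every `thin`-th post-burn-in state.
   Identical seed, configuration and input give a bitwise-identical
   ensemble.

The default configuration follows the study setup (burn-in $10^7$,
$10^7$ steps thinned by 100 into an ensemble of $10^5$, jump 0.1,
seed 1868). The tests and the acceptance script run scaled-down chains —
burn-in $10^5$ and $10^5$ steps thinned by 10 for the brain model, and
$5\times10^4$ steps for the one- and two-dimensional closed-form checks —
sizes chosen so the whole suite completes in well under a minute while
Monte-Carlo errors stay in the third decimal. Correctness is asserted
where ground truth exists: on polytopes whose posterior is a truncated
Gaussian, sample moments must match the closed-form truncated-normal
moments within three Monte-Carlo standard errors (standard errors computed
with an autocorrelation-time correction, since a Metropolis chain is not
i.i.d.); every kept sample must satisfy every constraint; and the
scaled-down brain ensemble's net-ATP range must bracket the FBA optimum.
For the brain run the glycerol-3-phosphate dehydrogenase flux is
additionally fixed to zero, because under measurement uncertainty an
active glycerol-phosphate shuttle can otherwise substitute for (and even
reverse) the malate–aspartate shuttle.

`autocorrelation()` and `plot()` (trace histograms with mean and sd per
panel) support convergence assessment by eye, the practical standard for
low-dimensional chains like these (the brain polytope has 5 free
dimensions once the measured constraints are fixed).

# Lsei-FBA: predicting flux changes from expression changes

Given a healthy reference flux distribution $x^{ref}$ and a table of
disease-vs-control fold changes, `lsei_fba()`:

1. Maps genes to reactions via the model's associations. By default the
   boolean structure is flattened and the **arithmetic mean of the linear
   fold changes** of a reaction's genes is used — the simplest defensible
   mapping. `policy = "minimum"` and `"geometric_mean"` are available, as
   is `structured = TRUE` (minimum over AND-complexes, chosen policy over
   OR-isoforms); none of these is the default because there is no
   empirical evidence favoring the more elaborate mappings.
2. Forms the rough estimate $b_r = x^{ref}_r \cdot fc_r$ for every
   reaction $r$ with expression data. Log2 input is converted to linear
   scale first — multiplying a flux by a fold change is meaningful only
   in linear space. The signed value is scaled, so a release flux stays a
   release flux under up-regulation; for reactions whose reference flux
   is negative this is a modeling choice (magnitude-and-sign scaling)
   that the interface makes explicit rather than hiding.
3. Minimizes $\sum_r (x_r - b_r)^2$ subject to $E x = f$ and
   $G x \ge h$ — least squares with equalities and inequalities. All rows
   are weighted equally (the objective is an unweighted sum of squares).
   Reactions without gene data, including the exchange fluxes, appear
   only through the constraints: **no disease exchange rate is fixed**,
   because uptake under the disease condition is exactly what the method
   must predict. The two fraction-derived constraints of the healthy
   problem are likewise dropped in the disease problem: they are
   condition-specific measurements, not network structure.

The solver (`solve_lsei()`) eliminates the equalities through the SVD
null-space parameterization and runs a primal active-set method whose
subproblems are solved with pseudo-inverses, so rank-deficient target
matrices are handled, and when the minimizer is non-unique along null
directions of $A$ the minimum-Euclidean-norm representative is returned
(deterministic, and the convention of standard `lsei` implementations).
Because the particular solution lies in the row space of the equalities
and orthogonally to the null-space coordinates, minimizing the
reduced-coordinate norm is equivalent to minimizing $\lVert x \rVert$.

Two structural properties make good sanity checks and are asserted in the
tests: fold changes identically 1 return $x^{ref}$ exactly (the reference
is feasible and attains objective 0), and the attained objective never
exceeds $\lVert A x^{ref} - b \rVert^2$.

```{r lsei}
fc <- synthetic_fold_changes(model,
  pathway_effects = c(oxphos = -0.9, tca = -0.75, glycolysis = -0.5, ppp = 1),
  noise_sd = 0.1, seed = 1)
pred <- lsei_fba(model, fit, fc)
round(100 * (pred$values / fit$values - 1))[
  c("R_HEX1", "R_ICDHxm", "R_AKGDm", "R_ATPS4m", "R_O2t")]
```

# The synthetic fold-change generator

`synthetic_fold_changes()` emulates the *shape* of microarray-derived
disease signatures in neurodegeneration: many modest, largely congruent
shifts within a pathway. Each gene of a pathway draws its log2 fold
change from $N(\mu_p, \sigma)$, genes outside the listed pathways from
$N(0, \sigma)$; pathway membership reuses the model's own annotations, so
the generator works for any annotated model. Defaults used in the
examples ($\mu$ between −0.9 and +1 log2 units, $\sigma = 0.1$) are in
the range of effect sizes reported for bulk expression studies of
affected brain tissue. What the generator deliberately does **not**
emulate: probe-level noise models, correlated gene modules that cross
pathway boundaries, cell-type composition shifts, and any coupling
between expression and actual enzyme activity. Passing tests on synthetic
tables therefore demonstrate that the *algorithmic pipeline* is correct
and directionally sensible — down-regulating oxidative-phosphorylation
genes must lower the predicted ATP synthase flux — not that predictions
from a real patient dataset would be accurate.

# Numerical choices

* Feasibility tolerance $10^{-9}$ (absolute); FVA uniqueness threshold
  $10^{-6}$ mmol/min; SVD rank tolerance $10^{-10}$ (relative).
* Simplex: Dantzig pricing with an automatic switch to Bland's rule to
  guarantee termination on degenerate polytopes; canonical
  irreversibility rows are folded into variable nonnegativity instead of
  slack rows.
* Infeasible problems report the constraint rows with the largest
  residuals at the least-infeasible point of simplex phase 1; unbounded
  problems name the reaction dominating the unbounded ray.
* Active-set LSEI: iteration cap 400; multiplier sign tolerance scaled to
  the largest multiplier.
* Mirror sampler: reflection cap 1000 per proposal; per-direction
  proposal scales as described above.
* Duplicate species references within one SBML reaction are summed into a
  single net coefficient before the stoichiometric matrix is built.

# Known limitations

* The LP and LSEI solvers are dense and intended for curated models up to
  a few hundred reactions, not genome-scale reconstructions.
* SBML import covers plain Level 2/3 core documents with BiGG-style
  `GENE_ASSOCIATION`/`SUBSYSTEM` notes; the FBC package's bounds and
  gene-product semantics are out of scope.
* The ensemble sampler assumes the posterior is proper on the polytope;
  a likelihood-flat *and* unbounded direction would make it improper, and
  the per-direction scale falls back to an arbitrary unit in that case.
* The brain fixture is a curated synthetic reconstruction; it reproduces
  the published healthy-brain ATP budget by construction and should not
  be mistaken for the original supplementary reaction tables.
* Hypergraph layouts are deliberately simple (layered ranks or a circle);
  the drawing contract is semantic — widths, colors, directions, labels —
  not aesthetic.
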