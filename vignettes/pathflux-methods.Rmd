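---
title: "pathflux: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pathflux: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pathflux is a constraint-based modeling toolkit built around three
optimization procedures used when turning a draft genome-scale metabolic
reconstruction into tissue- or condition-specific models: slack-flux
pathway gapfilling, transcriptome-driven model reduction, and
quadratic-programming (QP) fitting of model fluxes to measured fluxomics.
This vignette explains the models behind each procedure, the parameters
that matter, the numerical choices, and what the synthetic test world does
and does not establish.

## The modeling substrate

A model is a stoichiometric network: metabolites with compartments,
reactions with signed stoichiometries, flux bounds, and optional
gene-protein-reaction (GPR) rules, plus a designated biomass pseudo-reaction
whose flux is the growth proxy.  Steady state imposes $N v = 0$ where $N$
is the stoichiometric matrix and $v$ the flux vector.

**Exchange sign convention.** An exchange reaction touches exactly one
metabolite with coefficient $+1$, so positive exchange flux is uptake.
This convention is forced by the asymmetric media bound
$-\mathrm{cap} \le v_{ex,i} \le \mathrm{cap}\cdot\gamma_i$, where
$\gamma_i = 1$ exactly when the metabolite is in the growth medium: only
the uptake direction is gated by the medium, secretion is always open.
The cap defaults to 100 flux units for gapfilling and 50 for the QP fit;
internal reactions are capped at 100 (gapfilling, on decomposed
components) and 1000 (QP, with $-1000$ as the reversible lower bound).
All caps are configurable.

**Decomposition.** The two mixed-integer procedures decompose every
reversible reaction into non-negative forward and backward component
fluxes with $v = v_{for} - v_{rev}$.  Binary use variables $z$ with
$v \le \mathrm{cap}\cdot z$ and the exclusivity constraint
$z_{for} + z_{rev} \le 1$ prevent a reaction from carrying both directions
at once — without them, a reversible reaction could fake "activity" by
running a mass-balanced futile loop $v_{for} = v_{rev} > 0$.  This
exclusivity is the sole reason the formulations contain integer variables,
so pathflux only emits binaries for reactions that actually have both
components; everything else stays a pure LP column.

## Slack-flux gapfilling

Given a model, a database of candidate reactions with strictly positive
penalties $\gamma_{gapfill,i}$, and a medium, gapfilling asks for a
minimum-cost set of database additions (and optionally reverse-direction
uses of irreversible model reactions) that lets as many gene-associated
model reactions as possible carry flux.  Every activation-set reaction
(gene-associated reactions plus biomass) receives a slack variable
$\delta_i \in [0, 0.01]$ tied to

$$v_{for,i} + v_{rev,i} + \delta_i \ge 0.01,$$

so $\delta_i$ is forced to its ceiling exactly when the reaction carries
no flux; summing slacks counts inactive reactions.  The objective

$$\min\; a \sum_{i \in \text{activation}} \gamma_{activate,i}\,\delta_i
  \;+\; \sum_{i \in \text{candidates}} \gamma_{gapfill,i}\, v_i$$

uses *continuous* candidate fluxes rather than binary indicator costs,
which keeps the integer part of the program small.  The scaling factor $a$
(default 0.1, sensible range 0.01–0.25) trades the cost of leaving model
reactions inactive against the cost of adding candidates.

**Economics of the slack term.** Because $\delta \le 0.01$, the largest
possible saving from activating one reaction is $a\cdot\gamma_{activate}
\cdot 0.01$ (with defaults, $10^{-3}$), while the smallest possible cost of
an addition is $\gamma_{gapfill}\cdot 0.01$ (at least $10^{-2}$): an
addition driven purely by the activation term only pays off when it
unlocks many reactions at once.  At genome scale that is the common case;
on desk-scale networks it rarely is, which is why the package exposes
`require_growth`: a hard constraint $v_{biomass} \ge 0.01$ that makes
gapfilling behave like classical growth-restoring gapfilling while the
slack term still maximizes pathway activity on top.  By default biomass is
only a member of the activation set; `require_growth = TRUE` is what the
synthetic acceptance world uses.

**Penalties.** Candidate penalties default to a base of 1 plus additive
surcharges: +1 for transport reactions (those spanning more than one
compartment), +2 for use against the native direction (reversal
candidates), +1 for candidates flagged as having no gene in any source
organism; a uniform-1 mode is available.  These mirror common practice in
published gapfilling pipelines; the exact values are configuration, not
science.

**Alternate optima and determinism.** The MILPs here are degenerate.  After
the optimum $f^\ast$ is found, a second lexicographic stage minimizes total
component flux subject to the objective staying within a small tolerance of
$f^\ast$, which selects a canonical, reproducible solution.  The slack
variables are weighted heavily in the second stage so its tolerance window
cannot be spent trading slack for flux (shaving an active reaction to just
below the activity threshold).  A reaction is reported *active* when its
net flux is at least 0.01 — the same constant as the slack ceiling — with a
$10^{-6}$ solver-noise margin; this is deliberately coarser than solver
epsilon so the classification is stable.

## Expression scoring and reduction

Raw expression values for the focal condition are normalized per gene by
the median of that gene across all columns of the supplied matrix; genes
with median zero are unscorable and are excluded rather than pseudocounted
(a pseudocount would manufacture scores the data cannot support; an
optional pseudocount exists but is off by default).  Reaction scores
follow the GPR tree: the score of a reaction is the **max** over complexes
of the **min** over subunits of the **max** over each subunit's genes —
isozymes take the best gene, complexes are limited by their weakest
subunit.  Reactions scoring strictly below the threshold (default 0.2,
i.e. critical genes at 20% of their cross-condition median) are *low*
expression; a score of exactly 0.2 is high, reading "falling below" as a
strict inequality.  Reactions without a GPR, or with no scorable gene, are
*unscored* and take no part in the reduction objective.

Reduction re-uses the gapfilling machinery on the model's own
stoichiometry only (no database), with slack variables for the
high-expression set and flux costs on the low set:

$$\min\; a \sum_{high} E_i\, \delta_i + a \sum_{low} E_i\, v_i .$$

Both terms share $a$, so $a$ cancels in the arg-min; it is retained for
symmetry with gapfilling.  The trade-off is real in both directions: a
high reaction stays off when activating it requires more weighted
low-expression flux than its own weighted slack saving, and a low reaction
is used when cheap enough.  Growth is enforced as a hard constraint
($v_{biomass} \ge 0.01$) by default — every context-specific model should
grow on its construction medium — with an opt-out that instead places
biomass in the high set at weight 1.

**Pruning rule.** The final reduced model drops exactly the scored
low-expression reactions whose optimal net flux is numerically zero.
Inactive *high* reactions are retained: their genes are expressed, and a
single flux state is not evidence they are absent.  Unscored reactions,
exchanges and biomass are retained.  This reproduces the defining subset
property (reduced ⊆ parent) and keeps essential low-expression reactions —
anything the growth constraint forces to carry flux survives.  A single
optimum may idle reactions that alternate optima would use; the
lexicographic minimum-flux stage makes the choice canonical, and the
conservative retention of high and unscored reactions bounds the damage.
Flux-variability-based rescue of low reactions was considered and left
out of the default path (one flux state is what the procedure defines).

## QP flux fitting

Fitting minimizes $\sum_{measured} (v_{exp,i} - v_i)^2$ over the standard
FBA constraints with reversible reactions *not* decomposed: bounds
$[0\ \text{or}\ {-1000},\ 1000]$ internally and media-gated exchange
bounds with cap 50.  The projection onto measured coordinates is unique by
convexity; the full vector is canonicalized with a tiny ridge
($10^{-8}$ by default) on all coordinates, i.e. a minimum-norm secondary
objective for the unmeasured fluxes.  Fits are computed with the model
growing ($v_{biomass} \ge 0.01$, configurable to 0).  Fit quality is
summarized by the squared distance, the Spearman rank correlation between
measured and fitted values (midrank ties; exact permutation p-value for
$n < 10$, two-sided t-approximation otherwise), and the blocked-reaction
percentage: the share of reactions whose flux-variability interval is
exactly $[0, 0]$ under the same constraints, reported to one decimal.

Measured reaction names must be mapped to model ids explicitly (a
two-column mapping table); no fuzzy matching is attempted.

## Solver backend

All programs are formulated in R and handed as standard-form LP/MILP/QP to
a bundled Python worker using SciPy's HiGHS interface (`scipy.optimize.milp`)
and `trust-constr` for the QP, followed by an exact active-set KKT polish
(the Hessian is diagonal, so the free block decouples; the polished point
is accepted only if feasible and no worse).  A persistent worker process is
reused over a localhost socket, with a one-shot subprocess fallback.
Reported tolerances: integrality/feasibility at HiGHS defaults
($\sim 10^{-7}$), QP stationarity residuals below $10^{-6}$ on all test
fixtures, activity classification margin $10^{-6}$.

## The synthetic world

The fixture generators are first-class, tested code; everything they emit
is a pure function of a seed.  A generated model is a set of linear
pathways from exchangeable root metabolites through a gene-associated
transport step and chain reactions with continuous product coefficients in
$[0.7, 1.4]$ (so steady-state fluxes are distinct along a chain and rank
statistics are non-degenerate).  Core pathways feed a biomass drain that
demands 10 units of each terminal — at the minimum-growth state every core
reaction then carries more than the 0.01 activity level, which is what
makes the scaling-factor robustness property hold exactly on fixtures
rather than within an uncontrolled tolerance.  Peripheral pathways end in
a secretion exchange and are free to be on or off: they are what reduction
prunes.  Gapfill cases remove essential core reactions into a candidate
database padded with flux-capable but useless "leak" decoys, and the
planted minimum is *verified* by exhaustive enumeration of all database
subsets at generation time — never assumed.  Expression fixtures plant
5-fold-over-median scores on active pathways and 0.05 on the rest, with
optional multiplicative lognormal noise (the data source for the real
procedure is RNA-Seq; no noise model is prescribed there, and lognormal is
the simplest strictly positive choice).  Flux cases sample a vertex of the
fitting polytope via a random-objective LP under heterogeneous uptake
limits and add Gaussian noise.

What a green test establishes: the optimizers find verified global optima
on networks small enough to enumerate; classification boundaries,
invariants (subset, growth preservation, monotonicity, determinism) hold
exactly; recovery of planted structure is exact in the noiseless limit.
What it does not establish: behavior on genome-scale topologies (loops,
cofactor coupling, highly degenerate alternate optima at scale),
thermodynamic plausibility, or the numerical performance of the paper-scale
reconstructions — those need real reconstructions and data.  The gapfill
oracle fixtures in particular keep internal reactions irreversible so the
per-subset score is a pure LP; the binary exclusivity machinery is
validated separately on a hand-built toy where the LP relaxation provably
cheats.

## Degenerate inputs and edge cases

Empty GPR rules are `NULL` (unscored, not low).  A gene-associated
reaction whose substrate is unproducible simply ends up inactive at full
slack.  An empty candidate database reduces gapfilling to activation
maximization over the model alone.  Candidate reactions referencing
metabolites that occur nowhere else are dead ends by construction and are
dropped with a warning before solving.  Zero-variance vectors make the
Spearman rank correlation undefined; the fit flags it `NA` rather than
reporting a number.  An empty high-expression set is an error — there is
nothing to activate.

## Known limitations

* The solver bridge requires a Python with SciPy ≥ 1.9 on `PATH`
  (`options(pathflux.python=...)` to override); there is no pure-R solver
  fallback because the R library set targeted here ships none.
* MILP scalability is bounded by HiGHS; the package is routinely exercised
  at tens-to-hundreds of reactions, not tens of thousands.
* SBML support covers the FBC subset needed here (species, reactions,
  bounds, gene associations, objective); groups, annotations beyond the
  role/source/pathway notes, and units are not preserved.
* Reduction returns a single canonical optimum; biologically equivalent
  alternate reductions exist and are not enumerated.
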