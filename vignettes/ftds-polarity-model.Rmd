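---
title: "A kinetic model of Fat-Dachsous planar polarity in a row of cells"
author: "FtDsPolarity authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model of Fat-Dachsous planar polarity in a row of cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FtDsPolarity)
```

## The biological question

In the *Drosophila* wing, every cell points its hair distally. Upstream of
the core planar-cell-polarity proteins, the atypical cadherins Fat (Ft)
and Dachsous (Ds) bind heterophilically across the interface between
neighbouring cells, and the Golgi kinase Four-jointed (Fj) — expressed in
a distally rising tissue-level gradient — phosphorylates both: Ft
phosphorylation increases its affinity for Ds, Ds phosphorylation
decreases its affinity for Ft. `FtDsPolarity` implements a deterministic
kinetic model of this module in a one-dimensional row of cells and asks
which ingredients are needed for the Ft-Ds heterodimer to accumulate on
the distal edge of each cell.

## The model

Cell $i$ (cell 1 most proximal, cell $N$ most distal) carries an Fj
kinase activity $Fj^i$, a total Ds pool $Ds_T^i$ and a total Ft pool
$Ft_T$. Fj activity feeds phosphorylation through a Hill function

$$H(Fj) = \frac{Fj^{\,n}}{K^n + Fj^{\,n}},$$

and the only dynamical cell-intrinsic variables are the phosphorylated
pools:

$$\frac{dFt^p_i}{dt} = \alpha_{Ft}\,H(Fj^i)\,(Ft_T - Ft^p_i)
  - \beta_{Ft}\,Ft^p_i, \qquad
\frac{dDs^p_i}{dt} = \alpha_{Ds}\,H(Fj^i)\,(Ds_T^i - Ds^p_i)
  - \beta_{Ds}\,Ds^p_i.$$

Unphosphorylated pools follow by conservation, $Ft^u_i = Ft_T - Ft^p_i$
and $Ds^u_i = Ds_T^i - Ds^p_i$; cells are uncoupled in these equations.
Because phosphorylated Ft binds strongly and phosphorylated Ds weakly,
only the $Ft^p$–$Ds^u$ pair is modelled as forming the heterodimer. At
the edge joining cells $i$ and $i+1$ it forms in two orientations by mass
action:

$$\frac{dC}{dt} = k_{on}\,(Ft^p_i\,Ds^u_{i+1} + Ds^u_i\,Ft^p_{i+1})
  - k_{off}\,C .$$

Heterodimer formation happens at the membrane, phosphorylation in the
Golgi, so there is no feedback from $C$ onto the monomer pools. At steady
state the difference between a cell's distal and proximal edge
concentrations decomposes algebraically into two cell-own terms,

$$\Delta C_i = \frac{k_{on}}{k_{off}}\,(P_{Ft,i} + \mu\,P_{Ds,i}),
\qquad
P_{Ft,i} = Ft^p_i\,(Ds^u_{i+1} - Ds^u_{i-1}), \quad
P_{Ds,i} = Ds^u_i\,(Ft^p_{i+1} - Ft^p_{i-1}),$$

the sub-cellular polarity of the cell's own phosphorylated Ft and of its
own unphosphorylated Ds. The weight factor $\mu$ probes whether the two
mechanisms contribute equally: $\mu = 1$ reproduces exactly the
difference of adjacent edge steady states (this identity is a regression
test of the implementation), $\mu = 10$ boosts the Ds route, $\mu = 0.1$
the Ft route. In wild type $P_{Ds} > 0$ (phosphorylated Ft rises
distally) and $P_{Ft} < 0$ (unphosphorylated Ds falls distally), which is
why the sign analysis below fixes the labelling of the two terms.

## Parameters and profiles

```{r}
cfg <- defaultWildtypeConfig()
cfg$params
```

The defaults are 20 cells; $\alpha_{Ft} = \alpha_{Ds} = 2$,
$\beta_{Ft} = \beta_{Ds} = 0.1$ (per unit time); $n = 1$, $K = 250$;
$k_{on} = 1$, $k_{off} = 0.1$; $\mu = 1$. Concentrations are normalized:
$Ft_T = 1$ in every cell, and Fj and total Ds are scaled by their values
in the most distal cell. With activities at most 1 against $K = 250$, the
Hill coupling operates deep in its near-linear regime; the half-dozen
phenotypes below do not depend on that choice (see the sensitivity
sweep).

The model states gradient shapes, not magnitudes, so the generator makes
two documented choices:

* **Fj activity** rises linearly as $Fj^i = i/N$ rather than
  $(i-1)/(N-1)$: every cell keeps a strictly positive activity and the
  distal-most cell sits exactly at 1, matching the normalization
  convention. Either convention is "linearly increasing".
* **Total Ds** falls linearly with a drop of $s = 0.5$ over the row,
  $Ds_T^i = 1 + s\,(N-i)/N$ (1.475 proximally, 1 distally). The slope is
  a free magnitude; $s = 0.5$ makes every interior cell distally
  polarized in wild type while $\mu = 0.1$ reverses the distal-most
  cells — both headline outcomes — whereas $s = 1$ already tips the
  distal-most interior cell marginally proximal in wild type. The slope
  is configurable (`wildtypeProfiles(..., dsSlope = )`).

Initial phosphorylated levels are drawn uniformly within each cell's
conservation bounds from a seeded generator (`randomInitialState`); the
kinetics are linear with a unique globally attracting fixed point, so
every seed converges to the same steady state — which the test suite
checks to 1e-8 across ten seeds.

## Numerics

Integration uses the explicit forward-difference (Euler) scheme,
`integratePhospho`, with `dt = 0.1`. All modes are linear with rates
$\alpha H(Fj) + \beta$ and $k_{off}$, so the scheme is stable for
`dt < stabilityBound(profiles, params)` (about 18.5 at the defaults);
larger steps are refused rather than silently diverging. A closed-form
solution (`analyticRelaxation`, `steadyStatePhospho`) exists for every
mode and serves as the exact oracle in the tests; an adaptive `deSolve`
integration is a second, independent cross-check there. The Euler path is
first-order: halving `dt` halves the worst-case deviation from the exact
solution (about $2\times10^{-3}$ per unit initial deviation at
`dt = 0.1`).

Runs stop when the maximum absolute rate over all cells, species and
tracked edges drops below `tol = 1e-12`, then continue for a settling
phase of 30 relaxation times of the slowest mode (capped by
`tMax = 1000`). The settling phase matters: stopping at the rate
criterion alone leaves a residual of roughly `tol`/$\beta$ per state
variable, and several of the model's exact statements — $\Delta C \equiv
0$ when both gradients are flattened, an exactly unpolarized tissue when
Ft phosphorylation is lost — would otherwise be blurred by
residual-scale noise. Settled states sit at the floating-point fixed
point, and those identities hold to about $10^{-14}$ in the shipped
configuration. Convergence is reported at the criterion time, not the end
of settling.

Classification of $\Delta C_i$ (`classifyPolarity`) uses an absolute
tolerance of 1e-9 in normalized concentration units: distal above it,
proximal below its negative, unpolarized between. $\Delta C$ is defined
only for interior cells; boundary cells are reported as missing and
rendered one-sided in plots. One exception is deliberate: parameter
sweeps (`sensitivitySweep`) classify each sweep point relative to the
point's own asymmetry scale (`classifyTol * max |ΔC|`, floored at 1e-12,
two decades above settled-run noise). A Hill coefficient of 4 against
activities far below $K$ rescales every $\Delta C$ to around $10^{-11}$
while leaving the direction of polarity intact everywhere, and the
robustness question a sweep answers is about direction, not magnitude;
the floor keeps tissue whose asymmetry is pure numerical residue (e.g.
$\alpha_{Ft} = 0$) classified as unpolarized.

## The in-silico experiment panel

```{r}
res <- runExperiment("wild_type", seed = 1)
res
table(polarityLabels(res))
all(diff(edgeTotals(res)) > 0)
```

Wild type polarizes every interior cell distally and predicts, besides
the sub-cellular asymmetry, a tissue-level heterodimer gradient rising
proximal to distal. The perturbations mirror classical genetics:

```{r}
sapply(c("flatten_fj", "flatten_ds", "flatten_both",
         "fj_ft_dead", "fj_ds_dead"),
       function(k) table(factor(polarityLabels(runExperiment(k, seed = 1)),
                                c("distal", "proximal", "unpolarized"))))
```

* `flatten_fj` — uniform Fj overexpression (any positive level; the
  default is the wild-type maximum) makes $Ft^p$ uniform, so $P_{Ds}
  \equiv 0$ and no cell is distal: the Fj gradient is essential. With the
  Ds gradient still intact, the residual $P_{Ft}$ term is slightly
  negative, so "loss of asymmetry" manifests as no-distal rather than
  exactly zero $\Delta C$.
* `flatten_ds` — a flat Ds gradient leaves all cells distal: the Ds
  gradient is dispensable while Fj remains graded.
* `flatten_both` — both uniform gives $\Delta C = 0$ exactly.
* `fj_ft_dead` ($\alpha_{Ft} = 0$) — no phosphorylated Ft, hence no
  heterodimer at all and an unpolarized tissue.
* `fj_ds_dead` ($\alpha_{Ds} = 0$) — polarity is untouched: Ds
  phosphorylation by Fj is redundant for the asymmetry.

The $\mu$ sweep re-weights one wild-type steady state (the
phosphorylation dynamics do not involve $\mu$): $\mu = 10$ amplifies
asymmetry in every cell, $\mu = 0.1$ diminishes it and reverses the
distal-most interior cells while proximal ones stay distal.

```{r}
sw <- muSweep(c(0.1, 1, 10), seed = 1)
with(sw, tapply(label, mu, table))
```

## What the generator does and does not emulate

The synthetic profiles reproduce the modelled study conditions: smooth
linear tissue-level gradients, identical kinetics in every cell, and
random but conservation-respecting initial phosphorylation. Real wing
tissue has cell-to-cell expression noise, a second dimension, cell
divisions and rearrangements, feedback from the core PCP proteins, and
the three weaker Ft-Ds binding pairs — none of which are modelled here.
Passing tests therefore demonstrate the internal logic of the
gradient-readout mechanism, not quantitative agreement with imaging data.

## Problem sizes and runtime

All shipped analyses use the 20-cell row; a default run is about 3000
Euler steps of a 20-cell state plus 19 edges and completes in
milliseconds, so the full test suite and the experiment panel run in
seconds. The test oracles run at the same size, with 100-state random
batteries for the algebraic identities.

## Known limitations

One-dimensional tissue only; tissue-wide perturbations only (no mosaic
clones, hence no domineering non-autonomy); no stochastic kinetics; the
Hill parameters are shared between the Ft and Ds couplings by default
(per-substrate overrides are accepted); and the phenomenological mapping
from $\Delta C$ to hair orientation is outside the model.
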