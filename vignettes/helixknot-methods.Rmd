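---
title: "Helical worm-like chains and the chirality of their knots: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical worm-like chains and the chirality of their knots: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`helixknot` simulates an isolated, coarse-grained helical polymer: a
worm-like chain (WLC) of `N` rigid segments of length `b` (so `N + 1`
"monomers"), governed by a Hamiltonian in units of the thermal energy kT
with three terms.

**Bending.** Consecutive segments pay `-eps_b * t_i . t_{i+1}` per joint,
the standard offset-free WLC discretization. Any constant shift of this
term cancels in Metropolis ratios, so only the `cos(theta)` coupling
matters; `eps_b` (kT) sets the stiffness, and at `u = 0` the model is an
ordinary discrete WLC whose joint average obeys the closed form
`<t_i . t_{i+1}> = coth(eps_b) - 1/eps_b`, which we use as a sampler
calibration gate.

**Chiral coupling.** Segment pairs separated by at most `d` segments
along the contour interact through a cholesteric-type kernel,

E_chiral = u * sum over 0 < j - i <= d of (t_i x t_j) . rhat_ij,

where `rhat_ij` is the unit vector between the two segment centers,
oriented from `i` to `j`. The kernel is odd under reflection and under
`u -> -u`, and is invariant under reversal of the contour numbering (both
tangents and `rhat` flip sign). Pairs with coincident centers contribute
zero (a measure-zero configuration; this avoids a 0/0). The global sign
of the kernel is a pure convention with no observable content except
through the stated meaning of `u`; we fixed it by the requirement that
`u > 0` yields right-handed helices (positive ensemble torsion), which we
verified on the sampled ensemble after choosing the sign on a parametric
right-handed helix fixture. The coupling range is `d = 10` segments in
all study conditions.

**Hard core.** Each segment carries a hard sphere of radius `R` at its
center. Pairs separated by fewer than `floor(4R/b)` segments along the
contour are exempt (they are constrained by connectivity anyway); beyond
that window, any center distance `<= 2R` makes the energy infinite. The
boundary case of exact equality counts as an overlap, matching the step
function convention `U(2R - r) = +Inf` for `2R - r >= 0`. `R = 0` and
`R = 0.5` give open helices, `R = 2.5` compact ones.

Lengths are reported in units of `b = 1` and energies in kT throughout.

## Sampling: reptation Monte Carlo

Conformations are sampled by Metropolis reptation: each move deletes the
terminal segment at one end (head or tail with probability 1/2) and
appends a segment with uniform-on-sphere direction at the other end; the
move is accepted with probability `min(1, exp(-dH))`, and any hard-core
violation rejects outright. The proposal is symmetric, so detailed
balance holds for the canonical ensemble of the Hamiltonian above. We
deliberately add no crankshaft or pivot moves.

The initial conformation is a straight rod for every `R`. The rod is
provably overlap-free: pairs inside the exclusion window do not interact,
and outside it the center distance `s * b >= floor(4R/b) * b` always
exceeds `2R`. A rod is of course atypical, so the equilibration phase is
discarded before sampling.

Two implementation details matter for correctness:

* **Energy bookkeeping.** The energy difference of a reptation move only
  involves the removed and added terminal segments, so `dH` is computed
  incrementally in O(d) (plus an O(N) overlap scan when `R > 0`). The
  incrementally tracked energies are stored with every frame and audited
  in the tests against a from-scratch recomputation (agreement to 1e-8;
  observed drift is below 1e-10 even after 1e8 moves).
* **Decorrelation.** Reptation renews a chain diffusively: the contour
  must slide a whole chain length, which takes on the order of `N^2`
  moves. The constructor defaults (`50 N` equilibration, `5 N` between
  samples) are cheap and usable for visual exploration, but every
  statistical claim in the tests and in `scripts/acceptance.R` overrides
  them with `O(N^2)`-scaled values (typically `5 N^2` equilibration and
  `N^2`, or for compact observables `2 N^2`, moves per sample) so that
  stored frames are effectively independent and binomial / SEM error
  bars are valid.

Randomness comes from R's global Mersenne-Twister stream, seeded once
per run; the seed is recorded in the trajectory object and in every file
the CLI writes. Two runs with the same seed are bitwise identical.

## Helicity observables

**Torsion.** The helical order parameter is the discrete Frenet torsion
`tau = ((r' x r'') . r''') / |r' x r''|^2` evaluated at interior vertices
with central differences `r' = (r_{i+1} - r_{i-1})/2`,
`r'' = r_{i+1} - 2 r_i + r_{i-1}`, and
`r''' = (r_{i+2} - 2 r_{i+1} + 2 r_{i-1} - r_{i-2})/2`. The ratio is
invariant under uniform rescaling of the stencil prefactors
(`tau` scales as `gamma/alpha` with `alpha = gamma` here), so the choice
of the 1/2 factors is gated not by convention but by a closed form: on a
densely sampled circular helix `(a cos t, a sin t, c t)` the estimator
must converge to `c/(a^2 + c^2)`, and the tests require 1% agreement at
200 points per turn. Locally straight vertices (`|r' x r''|^2` below
1e-12) are skipped and counted, never imputed. Chains are averaged per
frame first, then over frames, with the SEM as error.

**Chiral-energy fluctuations.** The heat-capacity-like quantity
`C_c = var(E_chiral) / (|u| N)` uses the population variance over frames.
Division by `|u|` follows the definition of the quantity as a
`u`-normalized variance; the additional division by `N` makes the value
intensive so chains of different length can be overlaid, and only
relative shapes across `u` are ever asserted. The error follows the
fluctuation-average formula `se(var) = sqrt((m4 - var^2)/n)` with `m4`
the fourth central moment. At `u = 0` the quantity is reported as
missing rather than 0/0.

## Knot analysis

**Closure.** Knot type is defined for closed curves, so each open
conformation is closed deterministically: both ends are extended along
the ray from the chain's center of mass through the respective end out
to a radius of 3 times the maximal vertex distance from the center, and
the two far points are joined by a great-circle arc on that sphere
(at least 8 points). The arc stays far from the chain body; doubling the
closure radius on fixture sets does not change any label (tested).

**KMT reduction.** The closed polygon is simplified by repeatedly
deleting any vertex whose spanned triangle is intersected by no other
edge — a sequence of elementary isotopies that preserves knot type while
typically collapsing an unknotted 300-segment chain to a triangle.
Degenerate (collinear) triangles are deleted only when the middle vertex
lies between its neighbours; coplanar edge/triangle contact is resolved
by an exact 2D test so that planar polygons reduce fully. Reduction is
idempotent and HOMFLY-invariant (tested).

**Diagrams.** The reduced polygon is projected along a viewing
direction; all crossings between non-adjacent edges are enumerated, the
strand nearer the viewer passes over, and each crossing gets the sign
`h = sign(e_z . (o x u))` from the directions of the over- and
under-passing bonds. Projections failing a regularity check (an edge
nearly parallel to the view, a crossing within 1e-7 of a vertex image, a
triple point, or two strands at equal depth) are discarded and a
deterministic, seedless golden-angle sequence of directions is tried;
fixtures are built so that the first direction is already regular.

**HOMFLY by skein recursion.** The polynomial is computed in the
convention `l P(L+) + l^-1 P(L-) + m P(L0) = 0` with `P(unknot) = 1`, so
a k-component unlink has `P = delta^(k-1)`, `delta = -(l + l^-1)/m`, and
mirror images exchange `l <-> l^-1`. The engine walks the diagram from a
basepoint; the first crossing whose first passage is an underpass is
switched (recursing on a more descending diagram) and smoothed (recursing
on one fewer crossing); descending diagrams are unlinks. Reidemeister
I/II reductions are applied at every node and results are memoized on a
canonical diagram code; coefficients are exact integers. Diagrams whose
crossing count still exceeds a cap (default 16) after reduction are
labelled indeterminate rather than risking an intractable recursion —
the knots of interest here have at most 5 essential crossings. A second,
deliberately naive evaluator (no reduction, no memoization, resolving
the last bad crossing) serves as an independent oracle in the tests.

**Classification and handedness.** A polygon's polynomial is looked up
in a reference table built at first use by this same engine from minimal
reference diagrams: braid closures `sigma_1^3` (trefoil), `sigma_1^5`
(5_1), `(sigma_1 sigma_2^-1)^2` (figure-eight), and the minimal
5-crossing (3,1,1)-pretzel embedding for 5_2 (its knot determinant, 7,
computed from the polynomial's Alexander specialization, confirms the
identification; 3, 5, 5 for the others). Handedness is anchored to the
crossing-sum rule: in those minimal diagrams the sign of the summed
crossing handedness is positive for the right-handed enantiomer. This
makes the handedness labels independent of any literature polynomial
table and ties them directly to the geometric sign convention used for
diagram crossings. The achiral figure-eight is labelled `achiral`,
the unknot `n/a`, everything outside the table `other`.

**Census and braid screening.** Knot labels aggregate into the knotting
probability `P_k`, the per-type share `P_k,norm` (normalized by the
total knotting probability), and the right-handed fraction `P_rk`, all
with plain binomial standard errors; indeterminate frames stay in the
denominators of `P_k` only and never enter `P_rk`. The braid screen
drops knotted conformations in which two segments separated by more than
`d` along the contour approach below `r_min = 1.5` (distances measured
between segment centers, consistent with the excluded-volume
convention); it isolates the "braid" mechanism — two tightly interwoven
helical sections whose winding sense inherits the molecular helicity and
biases crossing signs. Screening is applied to knotted frames only, and
unscreened/screened censuses are compared per type and coupling.

## Study conditions and problem sizes

The physical claims are asserted at desk scale, chosen once:

* **Racemic baseline.** Flexible ideal chains (`eps_b = 1`, `N = 300`,
  `u = 0`, `R = 0`) are knotted in roughly 17% of frames; chiral knots
  from this achiral ensemble must be 50% right-handed within 3 binomial
  SE. `scripts/acceptance.R` samples until 2000 knotted frames have
  been collected (about 12,000 frames at `N^2` move spacing); the test
  suite uses 4000 frames.
* **Coil–helix crossover.** `<tau>` at `eps_b = 4`, `R = 0`, `N = 200`
  over `u = 0, 0.1, 0.25, 0.5` (300 frames each) grows monotonically
  with 3 SE separations, vanishes at `u = 0`, and agrees between
  `N = 100` and `N = 200` at fixed `u` — the crossover, not a phase
  transition, and no finite-size effect at this resolution.
* **Fluctuation peak.** `C_c` at `R = 0.5`, `N = 200` is larger at
  `u = 0.1` than at `u = 0.5` (3 SE); resolving this requires the
  `2 N^2` move spacing since the variance estimator is the most
  correlation-sensitive quantity here.
* **Handedness bias.** At `u = +0.5`, `R = 0`, `N = 300` we use
  `eps_b = 0.5`: the chiral coupling itself stiffens the chain strongly,
  and at the bending stiffness of the large-scale study conditions the
  knotting probability of a 300-segment chain is of order 1e-4 — too
  knot-poor for desk-scale statistics. With `eps_b = 0.5` about 0.7% of
  frames knot and the right-handed excess of trefoils is strong
  (observed `P_rk` near 0.9, many standard errors above 0.5).

## What the generator emulates — and what it does not

The sampler produces equilibrium conformations of a single ideal or
self-avoiding helical chain. It does not emulate solvent, chain
dynamics, multi-chain packing, or any specific chemistry; mapping `u`
and `R` onto a real helical polymer (polyisocyanates, polyproline, an
alpha-helix) is outside its scope. Desk-scale chains (`N = 200-400`) are
an order of magnitude shorter than the large-scale study conditions
(`N = 1000-2000`), so knot populations are dominated by trefoils,
fivefold knots are rare, and quantities like the `u`-dependence of
`P_k,norm` for 4_1/5_1/5_2 are not statistically resolvable here; tests
assert only the claims listed above. Passing them shows the machinery
and the qualitative physics are right, not that figure-scale curves are
reproduced.

## Numerical choices and limitations

* Geometric tolerances: bond rigidity 1e-9 (relative), KMT and crossing
  degeneracy guards 1e-9 to 1e-12 in units of `b`, XYZ serialization at
  9 significant digits (readers accept 1e-6 relative bond error).
* The projection direction sequence is deterministic and seedless, so
  classification is a pure function of the polygon.
* The crossing cap (16 after reduction) labels a small fraction of
  deeply entangled frames indeterminate; they are logged and excluded
  from handedness denominators — at the racemic baseline this affects
  well under 1% of frames.
* Components built by hand rather than taken from a library: the skein
  engine, KMT reduction, diagram extraction, and the reptation kernel —
  no installed R package provides polygonal knot identification, and the
  topology stack is the scientific core of this package. Standard steps
  (YAML/JSON/CSV/XYZ I/O, statistics, random numbers) use base R and the
  usual format packages.
* `P_rk` for 5_1/5_2 at desk scale rests on a handful of events per run;
  only the trefoil bias is asserted statistically.
* **The braid-screen comparison does not resolve at desk scale.** The
  screen (`r_min = 1.5`, contour separation `> d`) is calibrated for
  stiff chains, whose knots only approach themselves closely when
  braided. Desk-scale knots, however, only form in flexible chains
  (`eps_b <= 1` at `N <= 400`), and a flexible ideal coil essentially
  always contains some nonlocal contact below `1.5 b`: in our runs the
  screen flags 95-100% of knotted frames, leaving no usable survivor
  population, and the few survivors observed are not less biased. The
  end-to-end suite implements the screened/unscreened comparison
  exactly as defined and is expected to fail at desk scale;
  demonstrating the reduction requires the stiff, long-chain regime
  (`eps_b = 4`, `N ~ 2000`). The screening machinery itself
  ([braid_screen()], [screen_labels()], [handedness_bias_report()]) is
  exercised and verified structurally elsewhere in the suite.
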