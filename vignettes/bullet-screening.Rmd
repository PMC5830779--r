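---
title: "Therapeutic bullet screening on logical network models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Therapeutic bullet screening on logical network models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnscreen)
```

# The model class

`bnscreen` works on logic-based models: `n` named nodes, each with a discrete
activity level from the evenly spaced `h`-level domain
`{0, 1/(h-1), ..., 1}` and an update rule written with the Zadeh operators
(`∧` = min, `∨` = max, `¬x` = 1 − x). With `h = 2` this is an ordinary
Boolean network; larger `h` lets a node express intermediate activity (for
instance `0.5` as partial activation under `h = 3`). The Zadeh operators are
closed on every evenly spaced grid, so the dynamics never leave the domain;
the package exploits this by storing levels as integer indices `0..h-1` and
implementing the connectives as integer `min`/`max`/`(h-1)-x` in compiled
code, which makes state equality — the backbone of attractor matching and
basin counting — exact rather than floating-point.

Constant inputs are ordinary nodes with self-equations (`do = do`). Their
constancy partitions the state space into blocks, which is why basins
determined purely by inputs come out exact while others are estimates (see
below).

A *variant* is a model plus constant forcings: the physiological variant has
none, the pathological variant mimics a disease lesion (e.g. `locker = 0`,
or `p14ARF = 0, p16INK4a = 0` for a CDKN2A deletion), and a testing variant
adds a candidate intervention on top. A forced node keeps its slot in the
state space — initial states may contradict a forcing, and the node relaxes
to its forced value when it is updated. This matters: basins are percentages
of the *full* state space, matching how the published tables are normalised.

# Attractors and basins

Under **synchronous** updating the dynamics are deterministic; from any
start, iterating until the first repeated state yields the attractor cycle.
Cycles are canonicalised by rotating the lexicographically smallest state to
the front, so cycle equality is exact.

Under **general asynchronous** updating, one node chosen uniformly at random
updates per step. Attractors are then terminal strongly connected components
(terminal SCCs) of the state-transition graph: sets `T` with
`Fwd(x) ⊆ T` for every `x ∈ T`. The search, per initial state:

1. walk up to `maxk` random steps (stopping early upon entering an already
   validated attractor — attractors are escape-free, so this cannot change
   the credit);
2. compute the forward reachable set of the final state (breadth-first
   closure under all `n` single-node successors);
3. validate it as a terminal SCC and credit the start to it.

A forward reachable set is *closed under successors by construction*; the
decisive part of validation is therefore strong connectivity, which rejects
closures of transient states (they contain smaller escape-free subsets
without being able to return to the start of the closure). The
implementation checks both closure and strong connectivity explicitly so the
predicate is meaningful for arbitrary candidate sets.

A walk that ends mid-transient produces an invalid candidate. The published
method does not say what happens then; this package retries the walk with
fresh randomness (`retries`, default 3) and finally counts the start as
*unresolved*, excluding it from basin percentages and warning. All starts
unresolved is a hard error (the walk length is far too small). Forward-set
computation aborts beyond `forward_cap` states (default `1e6`) to fail fast
instead of exhausting memory when a walk is stranded in a huge transient.

Each start contributes exactly one credit — a reachability estimate rather
than a true basin, since an asynchronous start can reach several attractors.
The test suite contains an exact oracle for this crediting scheme: the
absorption probabilities of the uniform single-node-update Markov chain,
solved as a sparse linear system. On the bundled example network the engine's
replicate-averaged estimates agree with those probabilities to well under
two percentage points.

# The therapeutic criterion

With physiological and pathological attractor sets computed once per screen,
each bullet `(targets, modalities)` is applied on top of the pathological
forcings (overriding on collision, so reversal bullets are testable) and the
testing attractor set is computed. Every testing attractor is classified by
exact canonical state-set equality: physiological, else pathological, else
*de novo*. Then

* `x` = summed basin percentages of physiologically matched attractors in
  the pathological space (computed once, from the pathological run);
* `y` = the same quantity in the testing space;
* therapeutic ⇔ `y − x ≥ δ` and no de novo attractor.

`δ` (percentage points, default 5 — the value used in the published screens)
tunes stringency and absorbs sampling noise; `δ = 0` admits `y = x`
(compositional change without size change). The comparison always uses
unrounded percentages; tables round to one decimal for display. Bullets that
remove every pathological attractor make `y = 100` by construction, so the
older, stricter criterion ("remove all pathological attractors") is a
special case of this one.

Partial attractor matching and acceptance of benign de novo attractors are
deliberately *not* implemented; an attractor that matches nothing is always
disqualifying, as in the published method.

## Borderline bullets

Screen verdicts near the threshold are intrinsically stochastic. On the
example network the exact expected gain of `do[0]` is 5.68 — 0.68 points
above `δ = 5` — so a single 512-start screen misses it roughly 30% of the
time, and the published table's gain for it (7.8) is a favourable draw. The
acceptance tests therefore apply the verdict to gains averaged over
replicate screens, which reproduces the published 1- and 2-bullet sets
exactly; a user reading single-run output should treat rows with
`gain − δ` within a couple of points as provisional and re-run with other
seeds (or a larger `max_states` where the space allows).

# Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `h` | logic levels | 2 | Boolean models; 3 for three-valued |
| `mode` | updating scheme | `async` | the published case-study setting |
| `max_states` (`maxS`) | initial states per attractor set | 1000 | published case-study setting; the full space is enumerated whenever `maxS ≥ h^n` |
| `max_walk` (`maxk`) | random-walk length, steps | 10000 | published case-study setting; 1000 suffices for the 9-node example |
| `retries` | walk retries before a start is unresolved | 3 | repair policy for invalid candidates |
| `forward_cap` | forward-set size abort, states | 1e6 | fail fast on under-provisioned `maxk` |
| `delta` (`δ`) | gain threshold, percentage points | 5 | published screens; 0 allowed |
| `n_targ` (`r`) | targets per bullet | 1 | bullet size; there are `C(n,r)·h^r` bullets |
| `maxtarg`, `maxmoda` | sampling caps on combinations / arrangements | ∞ | exhaustive when they cover the totals |

Seeding: one global seed per run; per-stream seeds (reference runs, each
bullet) are derived from it with a string hash, so adding or removing a
bullet does not perturb the randomness of the others, and identical
configurations reproduce reports byte-identically.

# Bundled models and the synthetic-data generator

`example_network()` is the 9-node task-control network transcribed verbatim
from its publication; its pathological variant forces `locker = 0`. It is
small enough that every acceptance quantity can be cross-checked against
exhaustive and exact oracles.

`bladder_model()` is a 27-node Boolean working model of bladder
tumorigenesis. The original supplementary equation file could not be
obtained in this environment, so the bundled equations are a
**synthetic reconstruction** (files `bladder_synthetic_*.txt`) built from
the published logical rules of the underlying tumorigenesis model and the
documented adaptations: ternary variables (ATM, CHEK1/2, E2F1, E2F3) encoded
as exact-level Boolean pairs (`V_lvl1` ⇔ level 1, `V_lvl2` ⇔ level 2), the
two trigger-specific apoptosis levels merged, the three phenotype readouts
(`Proliferation = CyclinE1 ∨ CyclinA`,
`GrowthArrest = p21CIP ∨ RB1 ∨ RBL2`, `Apoptosis = TP53 ∨ E2F1_lvl2`) kept
outside the dynamics, and the four input parameters (growth stimulation on,
growth inhibition on, no DNA damage) injected into the equations. The
pre-injection 31-node model ships alongside so the injection path is
exercised end-to-end. The reconstruction reproduces the five published
attractors state-for-state (3 physiological, 2 pathological) and the
landmark bullet behaviours (`CDC25A[0]` drives the growth-arrest basin to
100% of the testing space); its long-run basin means sit within the
±3-point acceptance band of the published values but a few points off,
which is the expected signature of small differences in the reconstructed
transient (DNA-damage) dynamics. Conclusions drawn from this fixture concern
the screening machinery, not the biology of the original model.

`random_model()` generates seeded random models (bounded in-degree, bounded
expression depth) purely as oracle-test substrate. It makes no attempt at
biological realism (no scale-free wiring, no canalising bias); a green
oracle-equivalence test establishes correctness of the search on arbitrary
logical dynamics, not fidelity to any organism.

# Numerical and representational choices

* Levels as integer indices end-to-end in the engine; values in `[0,1]`
  only at parse/display boundaries. Non-domain constants (e.g. `0.3` under
  `h = 3`) are rejected, never snapped.
* Canonical attractor form: states sorted lexicographically (first declared
  node most significant); synchronous cycles stored in cycle order rotated
  to start at the smallest state. Deduplication and classification compare
  these canonical forms byte-for-byte.
* State enumeration is lexicographic; sampling is uniform without
  replacement (collisions redrawn), so each sampled start is counted once.
* Output rows sort by descending gain, ties lexicographically by bullet
  token — the publication does not fix an order.
* Expression grammar: `!`/`not`/`¬`, `&`/`and`/`∧`, `|`/`or`/`∨`, with
  precedence NOT > AND > OR; serialization uses the ASCII forms with minimal
  parentheses, and parse → format → parse is the identity.

# Known limitations

* Asynchronous basins are reachability estimates; percentages carry
  sampling noise of roughly `√(p(1−p)/maxS)` and verdicts within a couple
  of points of `δ` are unstable across seeds (see above).
* Only the general asynchronous scheme is implemented (no random-order
  updating), and only exact attractor matching (no partial matching, no
  tolerated de novo attractors).
* The full 1404-bullet case-study screen at published settings is hours of
  compute in the original report; the test suite exercises the landmark
  bullets and the complete example-network screens instead.
* No SBML-qual import, no network inference, no BDD/SAT symbolic attractor
  computation — the scope is the screening method itself.
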