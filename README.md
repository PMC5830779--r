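# bnscreen

Attractor-based screening of therapeutic targets in logic-based models of
biological networks.

## The problem

Logic-based models (Boolean networks and their multivalued extensions)
describe regulatory and signalling systems as nodes with discrete activity
levels and logical update rules. The attractors of such a model — the sets of
states its dynamics cannot leave — are commonly read as the phenotypes of the
modelled system. Given

* a **physiological variant** `f_physio` (the model as published) and
* a **pathological variant** `f_patho` (the model plus disease-mimicking
  constant forcings, e.g. a constitutively inactivated node or a deleted
  gene),

`bnscreen` searches for **bullets**: combinations of node forcings
`(c_targ, c_moda)` — `r` distinct targets, each held at a constant level
(0 = inhibition, 1 = activation, intermediate levels under multivalued
logic). A bullet is applied on top of the pathological forcings, giving a
**testing variant**, and is called **therapeutic** when it enlarges the part
of the state space that leads to physiological attractors:

```
x = 100 · |⋃ B_physio,i| / |S_patho|      (before)
y = 100 · |⋃ B_physio,i| / |S_test|       (after)
therapeutic  ⇔  y − x ≥ δ  and no de novo attractor appears
```

where `B_physio,i` are the basins of the attractors that match (by exact
state-set equality) an attractor of the physiological variant, and a *de
novo* attractor is one matching neither a physiological nor a pathological
attractor.

Attractors are found per updating scheme:

* **synchronous** — all nodes update at once; attractors are deterministic
  cycles found by iterating to the first repeated state;
* **general asynchronous** — one uniformly chosen node updates per step;
  attractors are terminal strongly connected components (terminal SCCs) of
  the state-transition graph, found by long random walks (`maxk` steps) from
  up to `maxS` initial states, validating the forward reachable set of the
  walk's end state. Basins are estimated by crediting each start to the
  attractor its own walk reaches, so basin sizes under asynchronous updating
  are reachability estimates subject to sampling noise.

Multivalued models use the Zadeh operators on an evenly spaced `h`-level
domain in `[0, 1]`: `x ∧ y = min(x, y)`, `x ∨ y = max(x, y)`, `¬x = 1 − x`.

## Worked example

The bundled 9-node task-control network has two constant inputs (a `do`
instruction and a `factory` that supplies energy) and a `locker` that must
stop the `task` when energy is missing. The pathological variant forces
`locker = 0`.

```r
library(bnscreen)
ex  <- example_network()
cfg <- search_config("async", max_states = 512, max_walk = 1000, seed = 1)

attractor_table(find_attractors(ex$physio, cfg),
                project = c("do", "factory", "energy", "locker", "task"))
#>   attractor basin_pct do factory energy locker task
#> 1        A1      18.2  0       0      0      1    0
#> 2        A2       6.8  0       0      1      0    0
#> 3        A3      25.0  0       1      1      0    0
#> 4        A4      25.0  1       0      0      1    0
#> 5        A5      25.0  1       1      1      0    1
```

Five single-state attractors: the three 25% basins are fixed exactly by the
two constant inputs (each input block of 128 states resolves to one
attractor); the 18.2/6.8 split is a reachability estimate. Screening all 18
single-target bullets on the pathological variant:

```r
screen_table(screen(ex$physio, ex$patho, n_targ = 1, delta = 5, config = cfg))
#>       bullet  x     y gain physio:A1 physio:A2 physio:A3 physio:A4 physio:A5
#> 1 factory[1] 57 100.0 43.0         0       0.0        50         0        50
#> 2      do[0] 57  62.9  5.9         0      12.9        50         0         0
#>   patho:A1 patho:A4 de_novo_count therapeutic
#> 1      0.0        0             0        TRUE
#> 2     37.1        0             0        TRUE
```

Keeping the factory permanently on (`factory[1]`) removes every pathological
attractor, pushing the physiological part of the testing space from 57% to
100%; abolishing the instruction (`do[0]`) is weakly therapeutic (gain ≈ 5.9,
an expected gain of 5.68 — right at the δ = 5 threshold). Forcing
`locker = 1`, the naive reversal of the disturbance, is *not* therapeutic.

A 27-node bladder-tumorigenesis case study (a validated synthetic
reconstruction of a published model, see the vignette) ships as
`bladder_model()`, with phenotype readouts (Proliferation, GrowthArrest,
Apoptosis) evaluated on attractors after the search.

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "bnscreen.R", package = "bnscreen"))')" \
  screen --model inst/extdata/example_physio.txt --force locker=0 \
  --targets 1 --delta 5 --max-states 512 --max-walk 1000 --seed 1 --out screen.tsv
```

Subcommands `attractors` and `screen`; reports are TSV with `#` metadata
lines and are byte-identical for identical configuration and seed.

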