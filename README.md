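# lbskappa

A modular rule-based modelling language for cellular signalling, compiled
to flat Kappa.

Rule-based languages of the Kappa family describe biochemistry as rewrites
of site graphs: agents (proteins) carry named sites with internal states
(phosphorylation, conformation, nucleotide loading, ...) and at most one
bond per site, and a rule such as

```
Raf{x~p} + MEK{S222~u} -> Raf{x~p!1}-MEK{S222~u!1}
```

applies in *any* context consistent with its pattern, which is what makes
the combinatorial complexity of signalling pathways tractable.  Flat Kappa
offers no structure above the single rule, though.  `lbskappa` implements a
high-level language for modellers who want that structure — parameterised
**modules** with agent subtyping, a **compartment** hierarchy with
transport rules, **complex abbreviation and update** expressions,
**aliases** for addressing protomers of homo-multimers, non-deterministic
agent **choice** (`or`), and compile-time **R script blocks** for
generating model text — together with:

* a compiler to flat Kappa in the KaSim v3 dialect (`lbsk_compile()`,
  `write_kasim()`), with per-rule link-label encoding, a
  compartment-encoding `comp` site and full well-typedness checking;
* an exact Gillespie simulator over explicit rule embeddings (`ssa()`,
  `find_embeddings()`) for desk-scale experiments;
* a fixture library of worked signalling models — a generic
  phosphorylation module, a MAPK cascade, the chemotactic flagellar switch
  ring, an insulin-signalling excerpt — with their known flat expansions
  (`fixture()`, `compile_fixture()`);
* a command-line front end (`inst/cli/lbsk.R`).

The concrete grammar is documented in `inst/grammar/lbsk.ebnf`; the methods
vignette (`vignettes/lbs-kappa.Rmd`) explains the semantics choices in
detail.

## Worked example

A generic phosphorylation module — bind, phosphorylate, unbind — is
defined once and instantiated with the kinase Raf (binding site `x`) and
the substrate MEK (site `S222`):

```r
library(lbskappa)
k <- lbsk_compile("
  module phosphorylate(agent k:{m}, s:{n}){
    k{m} + s{n~u} -> k{m!1}-s{n~u!1}|
    k{m!1}-s{n~u!1} -> k{m!1}-s{n~p!1}|
    k{m!1}-s{n!1} -> k{m} + s{n}
  };
  agent Raf = new {x, y};
  agent MEK = new {t, S218, S222};
  phosphorylate(Raf:{x}, MEK:{S222})|
  init Raf{x~u, y~u} 100 | init MEK{t~u, S218~u, S222~u} 100")
k
#> <kappa program: 3 rules, 2 init complexes, 2 agent kinds>
cat(write_kasim(k))
#> %agent: MEK(t~u~p,S218~u~p,S222~u~p,comp~top)
#> %agent: Raf(x~u~p,y~u~p,comp~top)
#> 'b1.r1' Raf(x, comp~top),MEK(S222~u, comp~top) -> Raf(x!1, comp~top),MEK(S222~u!1, comp~top) @ 1
#> 'b1.r2' Raf(x!1, comp~top),MEK(S222~u!1, comp~top) -> Raf(x!1, comp~top),MEK(S222~p!1, comp~top) @ 1
#> 'b1.r3' Raf(x!1, comp~top),MEK(S222!1, comp~top) -> Raf(x, comp~top),MEK(S222, comp~top) @ 1
#> %init: 100 Raf(x~u, y~u, comp~top)
#> %init: 100 MEK(S218~u, S222~u, t~u, comp~top)
```

The module body mentions only the sites it was given; the instantiation
substitutes `Raf.x` and `MEK.S222` and leaves Raf's `y` and MEK's other
sites unconstrained.  Simulating to `t = 5` (arbitrary time units) and
counting phosphorylated MEK (bound or free) and busy Raf:

```r
tr <- ssa(k, tmax = 5, seed = 1,
          observables = c(pMEK = "MEK{S222~p}", busyRaf = "Raf{x!_}"))
tail(tr, 1)
#>         time pMEK busyRaf
#> 466 4.713066   99       8
```

With no phosphatase in the model, 99 of the 100 MEK copies end up
phosphorylated and the count never decreases; 8 Raf molecules are mid-cycle
(bound) at the final event.  The same model compiles and simulates from the
shell:

```sh
Rscript inst/cli/lbsk.R compile model.lbsk -o model.ka
Rscript inst/cli/lbsk.R simulate model.lbsk --tmax 5 --seed 1 --obs "MEK{S222~p}" -o traj.csv
```

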