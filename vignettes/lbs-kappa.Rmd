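---
title: "A modular rule-based modelling language and its Kappa compilation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A modular rule-based modelling language and its Kappa compilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbskappa)
```

## The problem and the model

Rule-based languages in the Kappa family describe biochemistry as rewrites
of *site graphs*: an agent (typically a protein) has named sites, each
carrying an internal state (e.g. `u`/`p` for a phosphorylation state) and at
most one bond.  A rule matches any mixture context consistent with its
left-hand-side pattern, which tames the combinatorial explosion of species
in signalling pathways.  Flat Kappa, however, offers no structure above the
rule: large models are hard to read and maintain.

This package implements a high-level, modular language in that family and a
compiler down to flat Kappa (KaSim v3 dialect), plus a small exact
stochastic simulator.  The high-level constructs are:

* **agent definitions** — `agent Shc = new {PTB:(u p), Y318:(u p)};`
  creates a universally unique agent kind; repeating an identical definition
  creates a *distinct* kind.  Aliases (`agent P1, P2, P3 = new P{...}`)
  name one kind several times so that individual protomers of a
  homo-multimer can be addressed.
* **complex abbreviation and update** — a complex can be bound to an
  identifier and the right-hand side of a rule expressed as an *update*
  `c<Shc{Y318~p}>` of that identifier, touching exactly one agent and
  exactly the mentioned sites.
* **parameterised modules** with agent *subtyping*: an actual parameter may
  carry more sites and more agents than the formal requires, provided the
  annotated sites exist (with matching declared types).
* **compartments** — a tree of static compartments with cross-compartment
  transport rules.
* **non-determinism** — `agent M = MEK1 or MEK2;` groups functionally
  similar agents; a rule over choice agents expands to the cartesian
  product of concrete rules, co-varying each identifier across both rule
  sides.
* **embedded scripts** — R code blocks that generate model text at compile
  time (e.g. large initial conditions).

Compilation proceeds in four passes: parsing (`lbsk_parse()`), desugaring
(`lbsk_desugar()`), elaboration to located, fully typed normal-form rules
(`lbsk_elaborate()`), and translation to flat Kappa
(`lbsk_compile()`/`write_kasim()`).

## Semantics of omitted site components

A site expression has two components, internal state and link, and either
may be omitted.  Because every agent literal `Shc{Y318~p}` is sugar for the
update `Shc<Shc{Y318~p}>`, the omission rule inside updates fixes the
meaning of all rule-side patterns.  The package resolves omissions
asymmetrically:

* an omitted **internal state** is the *identity*: the state of the
  underlying value is untouched.  `Raf{x!1}` constrains/rewrites the bond
  of `x` but says nothing about its internal state;
* an omitted **link** is the *free link*, which overwrites: `Raf{x}`
  demands (on a LHS) or produces (on a RHS) a free site.  A bond is kept
  only by asking for the identity link explicitly with `!e`, as in
  `c<s{m~p!e}>` — phosphorylate `m` but leave the enzyme–substrate bond in
  place.

This is the only reading under which the worked flat expansions of the
module examples come out token-for-token: binding rules must find their
sites free and unbinding rules must free them, while untouched sites of a
complex (and internal states not mentioned) must persist.  Sites never
mentioned at all keep the default expression — wildcard internal state,
wildcard (`?`, free-or-bound) link — and are simply not printed in the flat
output, which is exactly what an unmentioned site means in Kappa.

One consequence is policed at translation time: a `?` or `!_` link may
appear on a rule's right-hand side only where it *preserves* — the
positionally matched reactant agent carries the same link kind on that site
(this occurs naturally when a constrained-but-unmodified agent, e.g. a
kinase written with `S222~p?`, appears on both sides).  A genuinely new
link wildcard in a product is rejected with the offending rule label.

## Modules, renaming and link-label namespaces

A module formal such as `agent c000: P1{f:(0 1)}-P2{f:(0 1)}-P3{f:(0 1)}`
is an identifier plus an *annotation* listing the agents and sites the body
will address.  At invocation the actual's annotation is matched item by
item and a renaming `(formal agent name, formal site name) -> (actual
agent name, actual site name)` is built; the body is elaborated with the
formal identifier bound to the actual value and all update targets and site
names resolved through the renaming.  Annotations written inside a module
body are themselves resolved through the enclosing renaming before being
matched, which is what makes nested invocations such as
`flip(c000:P2{f}, 1, 200)` work.

Two design points deserve note:

* **Site types at the boundary.**  A formal site with an explicitly
  declared type (e.g. `f:(0 1)`) requires the actual site's declared value
  set to be equal.  A formal with no declared type accepts any actual type:
  a cycle module that only *binds* its kinase on site `m` can be
  instantiated with `Ras:{n}` whose `n` carries `(gtp gdp)` states.  Any
  internal value the body actually uses on that site is still checked
  against the actual's type during elaboration, so the check is deferred,
  not dropped.
* **Link-label capture.**  Labels written in a module body live in a
  *namespace*, a bit-string extended at every invocation with the binary
  representation of a global invocation counter.  Labels carried by actual
  parameter values keep the namespace of the scope that created them.  Two
  sibling invocations of a body using label `1`, or a body label `1`
  meeting a parameter bond also labelled `1`, can therefore never alias.
  At translation, the distinct `(label, namespace)` pairs of each rule are
  renumbered to consecutive integers in first-occurrence order; since Kappa
  labels are rule-scoped, this per-rule encoding is observably equivalent
  to a single global injective encoding.

`as` bindings (`... -> k{m!1}-s{m~u!1} as c;`) are accepted on either side
of a rule and desugar to an agent definition hoisted in front of the rule,
scoping over the remainder of the enclosing block.

## Translation to flat Kappa

A normal-form agent's site map is linearised in lexicographic byte order of
site names, dropping sites whose expression is the double wildcard.  The
compartment path of every agent is encoded as a distinguished final site
`comp` whose internal state is the dot-joined root-to-leaf path
(`cell.nucleus`), with `top` for the empty path, so agents in different
compartments are distinct patterns.  Compartments must be declared —
`comp cell;` and `comp nucleus inside cell;` — a concrete syntax this
package fixes, since declarations appear only in the abstract syntax of the
language; the hierarchy is checked (declared parent, no cycles) wherever a
location is used.

Printable agent names resolve as: the declared name when globally unique
among `new` definitions; the defining identifier on collision (`MEK1`,
`MEK2` for two `new MEK{...}` definitions, matching the convention of the
worked expansions); a numeric suffix as a last resort.  `%agent:`
signature lines (required by KaSim) list each site's declared internal
values plus the `comp` site with the compartment tokens actually used.

Well-typedness is enforced at translation: unique site names per agent,
every link label exactly twice per rule side, ground initial conditions
(no wildcards — inits must mention every declared site).

## Embedded scripts

`scriptdef { ... }` blocks accumulate R definitions into a script
environment (a plain string, concatenated in scope order; later definitions
shadow earlier ones).  A `script { ... }` block is evaluated under that
environment and must produce a string, itself a program with a *hole* at
the end; the block's continuation is parsed into the hole and compilation
recurses.  Scripts run in a restricted evaluation environment exposing only
string/sequence helpers (`paste0`, `sprintf`, `seq_len`, ...): no
filesystem, network or package access, so compilation is deterministic.
Script evaluation is off by default (`allow_scripts = FALSE`, CLI
`--allow-scripts`).

The shipped script fixtures are transliterations of F#
originals, kept as comments alongside.  Two transcription corrections are
deliberate: the ring-construction script emits ground internal states
(`s~u`, `x~0`, `y~0`) because initial conditions must contain no
wildcards, and its curly-brace agent syntax follows the dialect used
everywhere else (the original prints parenthesis syntax).  The original's
modulo indexing also produces a label `0`, which the parser accepts and
the translator renumbers from 1.

## The simulator

`ssa()` is Gillespie's direct method over an explicit mixture of ground
agents.  A rule's activity is its rate constant times the exact number of
*embeddings* — injective, constraint-respecting matches of its LHS — with
**no automorphism division**, matching KaSim's convention (so a
homodimerisation rule `A{s} + A{s} -> ...` counts ordered pairs).  The
applied embedding is drawn uniformly; waiting times are exponential; a
fixed seed gives a bit-reproducible trajectory whose seed is recorded as an
attribute.

Event application matches reactants to products positionally for as long
as agent names agree; the unmatched remainder is deleted (left) or created
(right), so `mRNA -> MEK{S222~u}` deletes the mRNA and creates a MEK.
Created agents receive the first declared internal value on any site the
rule leaves unspecified, and deletion frees the partners of any bonds it
severs (Kappa's side-effect semantics).  Observable patterns use one
deliberate convention of their own: an omitted link is *unconstrained*, so
`MEK{S222~p}` counts phosphorylated MEK bound or not; write `!_` or an
explicit free site to constrain it.  A hard cap (default `1e5` agents, and
an event cap) keeps runs at desk scale; exhausted activity terminates early
and is reported in the trajectory's `status` attribute.

## Fixtures, generators, and what the tests show

The fixture library transcribes the worked models: the phosphorylation
module and its three-rule flat expansion, the complex-update pair, the
four-rule MEK/ERK choice expansion, the chemotactic switch ring (16
directed rules pairing into 8 reversible ones), the MAPK cascade (30 rules;
6 per cycle), an insulin-signalling excerpt (whose `bpu3`/`pho`/`unbind`
module skeletons and agent signatures are minimal synthetic
reconstructions, the full model not being transcribed), and the two script
examples.  Where the source prints the flat expansion in full, the
compiled output is compared token-for-token after canonicalisation
(`kappa_canonical()`: labels renumbered in first-occurrence order,
complexes grouped, rules sorted).

`random_model()` generates models whose directed-rule count is known by
construction (two-rule bind/unbind modules plus one degradation rule over
binary choice agents inside a compartment): it exercises `new`, literal
updates, modules, choice and compartments, but *not* deep module nesting,
reversible rules, scripts, or adversarial name shadowing — passing the
property sweep therefore shows the expansion arithmetic and
well-typedness, not full-language coverage.  The simulator's statistical
check uses a linear death process (40 agents, rate 0.25, horizon 2 time
units, 200 replicates) against the closed form `n0*exp(-k*t)`; embedding
counts are checked against a brute-force all-injections oracle on mixtures
of at most 20 agents.  These problem sizes keep the whole suite in the
tens of seconds on one CPU.

## Known limitations

* No static type system for link labels: dangling-bond and duplicate-site
  errors surface at translation, with the rule label, not at definition
  time.
* Choice co-varies only through identifiers; an `or` written inline in a
  rule expands each occurrence independently.
* Compartment module parameters are supported only as aliases; update
  expressions do not take compartment path prefixes (no worked example
  exercises either).
* No BNGL or SBML emission, no KaSim process invocation, no `%mod:`
  perturbations, and no performance ambitions for the simulator — the
  reference stochastic engines remain the tools of choice for large
  mixtures.
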