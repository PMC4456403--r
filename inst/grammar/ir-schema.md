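# Intermediate-representation JSON (`--dump-ir`)

`lbsk compile IN --dump-ir OUT.json` serialises the elaboration result
(normal-form rules and initial populations, before Kappa translation):

```json
{
  "rules": [
    {
      "label": "b1.r1",          // rule name: namespace + global counter
      "rate": 1,
      "lhs": [ <value>, ... ],   // one value per '+'-separated term
      "rhs": [ <value>, ... ]
    }
  ],
  "inits": [ { "count": 100, "value": <value> } ],
  "agents": {                    // registry of `new` definitions, by uid
    "a1": { "name": "Raf", "defid": "Raf", "sig": { "x": ["u","p"] } }
  }
}
```

A `<value>` is a complex: an array of agents, each

```json
{
  "path": ["cell","nucleus"],    // compartment path, [] for top level
  "agent": "Shc",                // declared agent name
  "defid": "Shc",                // defining identifier
  "alias": "P2",                 // alias referenced through, if any
  "sites": {
    "Y318": {
      "type": ["u","p"],         // declared internal values
      "internal": "p",           // or "?" (wildcard)
      "link": "3@01"             // label@namespace, or "." free,
                                 // "_" bound, "?" free-or-bound
    }
  }
}
```

Link labels are still namespaced pairs at this level; the per-rule integer
encoding happens in the Kappa translation.
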