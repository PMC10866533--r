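{
  "comment": "Clarke error-grid boundary geometry. Zones are evaluated in order; within a zone, clauses are OR-ed and predicates AND-ed. Each predicate is the half-plane a*ref + b*pred + c (op) 0 with op in {le, ge, lt, gt}. Pairs matching no zone fall into the fallback zone.",
  "fallback": "B",
  "zones": [
    {
      "name": "A",
      "clauses": [
        [
          {"a": 1, "b": 0, "c": -70, "op": "le"},
          {"a": 0, "b": 1, "c": -70, "op": "le"}
        ],
        [
          {"a": -1.2, "b": 1, "c": 0, "op": "le"},
          {"a": -0.8, "b": 1, "c": 0, "op": "ge"}
        ]
      ]
    },
    {
      "name": "E",
      "clauses": [
        [
          {"a": 1, "b": 0, "c": -180, "op": "ge"},
          {"a": 0, "b": 1, "c": -70, "op": "le"}
        ],
        [
          {"a": 1, "b": 0, "c": -70, "op": "le"},
          {"a": 0, "b": 1, "c": -180, "op": "ge"}
        ]
      ]
    },
    {
      "name": "C",
      "clauses": [
        [
          {"a": 1, "b": 0, "c": -70, "op": "ge"},
          {"a": 1, "b": 0, "c": -290, "op": "le"},
          {"a": -1, "b": 1, "c": -110, "op": "ge"}
        ],
        [
          {"a": 1, "b": 0, "c": -130, "op": "ge"},
          {"a": 1, "b": 0, "c": -180, "op": "le"},
          {"a": -1.4, "b": 1, "c": 182, "op": "le"}
        ]
      ]
    },
    {
      "name": "D",
      "clauses": [
        [
          {"a": 1, "b": 0, "c": -240, "op": "ge"},
          {"a": 0, "b": 1, "c": -70, "op": "ge"},
          {"a": 0, "b": 1, "c": -180, "op": "le"}
        ],
        [
          {"a": 1, "b": 0, "c": -58.333333333333336, "op": "le"},
          {"a": 0, "b": 1, "c": -70, "op": "ge"},
          {"a": 0, "b": 1, "c": -180, "op": "le"}
        ],
        [
          {"a": 1, "b": 0, "c": -58.333333333333336, "op": "ge"},
          {"a": 1, "b": 0, "c": -70, "op": "le"},
          {"a": -1.2, "b": 1, "c": 0, "op": "ge"}
        ]
      ]
    }
  ]
}
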