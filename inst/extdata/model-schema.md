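# JSON model dialect

A metabolic model is one JSON object:

```json
{
  "species_id": "fermenter_1",
  "biomass_reaction_id": "BIOMASS",
  "metabolites": [
    {"id": "glc", "name": "D-glucose", "is_dietary": true}
  ],
  "reactions": [
    {
      "id": "EX_glc",
      "stoichiometry": {"glc": -1},
      "lower_bound": -1000,
      "upper_bound": 1000,
      "is_exchange": true,
      "ec_numbers": [],
      "pathways": []
    },
    {
      "id": "BIOMASS",
      "stoichiometry": {"glc": -10},
      "lower_bound": 0,
      "upper_bound": 1000,
      "is_exchange": false,
      "ec_numbers": ["2.7.1.1"],
      "pathways": ["glycolysis"]
    }
  ]
}
```

Rules:

- `species_id` and `biomass_reaction_id` are required; the biomass reaction
  must appear in `reactions`.
- `stoichiometry` maps metabolite id to a signed coefficient (negative =
  consumed); every id must be declared under `metabolites`.
- Bounds are flux limits in mmol/gDW/h with `lower_bound <= upper_bound`.
- Exchange reactions are marked with the explicit boolean `is_exchange`
  (never inferred from an `EX_` naming convention) and touch exactly one
  metabolite; negative exchange flux is uptake, positive is secretion.
- `ec_numbers` and `pathways` are optional annotation arrays.
- `is_dietary` is derived from a diet table and kept consistent by
  `mark_dietary()`.

`write_model()` followed by `read_model(format = "json")` reproduces the
model exactly.
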