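{
  "comment": "Hand-derived expected outcomes for fixture_report.tsv (5 precursors x 6 runs x 2 channels, min_heavy_runs = 5 = ceil(0.8*6)). Derived by manual application of the filter inequalities; see each precursor's role in the fixture header of the tests.",
  "n_rows": 60,
  "min_heavy_runs": 5,
  "anchored": 4,
  "anchored_ids": ["AAAS(UniMod:21)AAK_2", "EEES(UniMod:21)EEK_2", "GGGT(UniMod:21)GGR_2", "LLLS(UniMod:21)LLR_2"],
  "retained": 2,
  "retained_ids": ["AAAS(UniMod:21)AAK_2", "GGGT(UniMod:21)GGR_2"],
  "absence_calls": 1,
  "absence_ids": ["LLLS(UniMod:21)LLR_2"],
  "labelfree_rows": 30,
  "heavy_pass_counts": {
    "AAAS(UniMod:21)AAK_2": 6,
    "GGGT(UniMod:21)GGR_2": 5,
    "VVVY(UniMod:21)VVK_2": 0,
    "LLLS(UniMod:21)LLR_2": 6,
    "EEES(UniMod:21)EEK_2": 6
  }
}
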