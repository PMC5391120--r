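{
  "comment": "Plausible mixing-matrix presets for learning-curve experiments, ordered by ascending noise amplification factor. Pi3 contains the sequence [2/10, 8/10]; dropping it yields Pi2, which has a lower NAF. These are synthetic presets shipped with the package, not measured configurations.",
  "presets": {
    "pi1": {
      "group_names": ["seq_high_target", "seq_low_target"],
      "rows": [["9/10", "1/10"], ["1/20", "19/20"]]
    },
    "pi2": {
      "group_names": ["seq_half", "seq_sparse"],
      "rows": [["5/10", "5/10"], ["1/10", "9/10"]]
    },
    "pi3": {
      "group_names": ["seq_half", "seq_mid", "seq_sparse"],
      "rows": [["5/10", "5/10"], ["2/10", "8/10"], ["1/10", "9/10"]]
    },
    "pi4": {
      "group_names": ["seq_a", "seq_b"],
      "rows": [["4/10", "6/10"], ["2/10", "8/10"]]
    },
    "study": {
      "group_names": ["sequence1", "sequence2"],
      "rows": [["3/8", "5/8"], ["2/18", "16/18"]]
    }
  }
}
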