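# Classic Graeb IVH scale: lateral ventricles scored 1 (trace of blood)
# to 4 (full of blood and expanded); third and fourth ventricles scored
# 1 (blood present) or 2 (filled with blood and expanded). Maximum 12.
name: classic
expansion_bonus: 0
full_fill: 0.999
compartments:
  - name: lateral_left
    ventricle: lateral_left
    trace_score: 1
    fill_scores:
      - {max: 0.5, score: 2}
      - {max: 1.0, score: 3}
    full_expanded_score: 4
  - name: lateral_right
    ventricle: lateral_right
    trace_score: 1
    fill_scores:
      - {max: 0.5, score: 2}
      - {max: 1.0, score: 3}
    full_expanded_score: 4
  - name: third
    ventricle: third
    trace_score: 1
    fill_scores:
      - {max: 1.0, score: 1}
    full_expanded_score: 2
  - name: fourth
    ventricle: fourth
    trace_score: 1
    fill_scores:
      - {max: 1.0, score: 1}
    full_expanded_score: 2
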