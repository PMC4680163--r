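# Modified Graeb scale: eight ventricular compartments each scored by
# quartile of blood filling (1: <=25% ... 4: >75%), summing to a maximum
# of 32. The per-ventricle expansion point is exposed as expansion_bonus
# (0 by default so the printed maximum of 32 holds; setting it to 1
# raises the attainable maximum accordingly).
name: mgs32
expansion_bonus: 0
full_fill: 0.999
compartments:
  - name: frontal_body_left
    ventricle: lateral_left
    trace_score: 1
    fill_scores:
      - {max: 0.25, score: 1}
      - {max: 0.50, score: 2}
      - {max: 0.75, score: 3}
      - {max: 1.00, score: 4}
  - name: frontal_body_right
    ventricle: lateral_right
    trace_score: 1
    fill_scores:
      - {max: 0.25, score: 1}
      - {max: 0.50, score: 2}
      - {max: 0.75, score: 3}
      - {max: 1.00, score: 4}
  - name: temporal_left
    ventricle: lateral_left
    trace_score: 1
    fill_scores:
      - {max: 0.25, score: 1}
      - {max: 0.50, score: 2}
      - {max: 0.75, score: 3}
      - {max: 1.00, score: 4}
  - name: temporal_right
    ventricle: lateral_right
    trace_score: 1
    fill_scores:
      - {max: 0.25, score: 1}
      - {max: 0.50, score: 2}
      - {max: 0.75, score: 3}
      - {max: 1.00, score: 4}
  - name: occipital_left
    ventricle: lateral_left
    trace_score: 1
    fill_scores:
      - {max: 0.25, score: 1}
      - {max: 0.50, score: 2}
      - {max: 0.75, score: 3}
      - {max: 1.00, score: 4}
  - name: occipital_right
    ventricle: lateral_right
    trace_score: 1
    fill_scores:
      - {max: 0.25, score: 1}
      - {max: 0.50, score: 2}
      - {max: 0.75, score: 3}
      - {max: 1.00, score: 4}
  - name: third
    ventricle: third
    trace_score: 1
    fill_scores:
      - {max: 0.25, score: 1}
      - {max: 0.50, score: 2}
      - {max: 0.75, score: 3}
      - {max: 1.00, score: 4}
  - name: fourth
    ventricle: fourth
    trace_score: 1
    fill_scores:
      - {max: 0.25, score: 1}
      - {max: 0.50, score: 2}
      - {max: 0.75, score: 3}
      - {max: 1.00, score: 4}
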