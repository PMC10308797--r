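# Segment C: adaptive biomarker-enrichment phase II then phase III RCT in the
# selected subpopulation
segment: C
n_reps: 200
seed: 1
designs:
  phase2:
    n2: 130
    cutoffs: [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9]
    stage_fractions: [0.5, 0.25, 0.25]
    alpha: 0.05
    min_subgroup_pairs: 5
  phase3: {alpha: 0.05, target_power: 0.9, max_total: 400}
scenario: {type: logistic, crossing: 0.6, slope: 5, orr0: 0.4}
enrollment: {rate_a: 4, rate_b: 10, gap_months: 6, followup_a: 6, followup_b: 6}
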