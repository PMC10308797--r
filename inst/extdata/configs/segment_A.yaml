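# Segment A: single-arm phase II (exact binomial) then phase III RCT (Fisher)
segment: A
n_reps: 200
seed: 1
designs:
  phase2: {n2: 60, orr0: 0.4, orr1_alt: 0.6, alpha: 0.05}
  phase3: {alpha: 0.05, target_power: 0.9, max_total: 400}
scenario: {orr1: 0.6, orr0: 0.4}
enrollment: {rate_a: 4, rate_b: 10, gap_months: 6, followup_a: 6, followup_b: 6}
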