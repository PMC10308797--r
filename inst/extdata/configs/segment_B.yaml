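# Segment B: phase I CRM dose finding then fixed-size single-arm phase II
segment: B
n_reps: 200
seed: 1
designs:
  phase1:
    n1: 20
    skeleton: [0.05, 0.12, 0.25, 0.40, 0.55, 0.68]
    tox_target: 0.25
    prior_sd: 1.34
    start_dose: 3
    no_skip: true
  phase2: {n2: 42, orr0: 0.4, orr1_alt: 0.6, alpha: 0.05, tox_monitor_threshold: 0.25}
scenario:
  tox: [0.02, 0.06, 0.12, 0.20, 0.35, 0.50]
  orr: [0.15, 0.30, 0.50, 0.60, 0.65, 0.67]
enrollment: {rate_a: 2, rate_b: 4, gap_months: 6, followup_a: 3, followup_b: 6}
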