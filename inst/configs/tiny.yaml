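# Desk-scale study configuration: a small synthetic cohort and a training
# schedule sized for a single CPU. Used by the package's own experiments.
experiment:
  l: 32
  ff: 64
  cycles: 1
  k_pre: 45
  k_fit: 55
  batch_size: 32
  batch_patients: 8
  lr: 5.0e-4
  lr_pretrain: 2.0e-3
  eps: 0.5
  theta: 0.3
  max_len: {diagnosis: 12, drug: 32, symptom: 6}
synthetic:
  n_diag_leaves: 50
  n_drug_leaves: 100
  n_symptoms: 30
  n_single_visit_patients: 2000
  n_multi_visit_patients: 300
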