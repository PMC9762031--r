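# Full defaults: the published architecture settings (2 encoder layers with
# 4 heads, 4 ontology-attention heads, learning rate 5e-4, 4:1:1 split)
# with the package's own choices elsewhere.
experiment:
  l: 64
  ff: 128
  cycles: 3
  k_pre: 5
  k_fit: 10
  batch_size: 64
  batch_patients: 16
  lr: 5.0e-4
  lr_pretrain: 1.0e-3
  eps: 0.5
  theta: 0.3
  max_len: {diagnosis: 32, drug: 72, symptom: 8}
synthetic:
  n_diag_leaves: 50
  n_drug_leaves: 100
  n_symptoms: 30
  n_single_visit_patients: 2000
  n_multi_visit_patients: 300
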