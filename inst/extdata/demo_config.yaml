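# Desk-scale demonstration study: same structure as the defaults, smaller
# cohorts so a full run finishes in a couple of seconds.
sim:
  n_cancer: 50
  n_benign: 40
  n_healthy: 50
  n_tumor_tissue: 10
  n_wbc: 10
  n_regions: 40
  n_true_dmr: 6
cv:
  n_repeats: 5
top_k: 20
n_boot: 200
seed: 4
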