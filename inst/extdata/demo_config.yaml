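# Demonstration pipeline configuration: small synthetic four-area recording
# with the default directed chain 1 -> 2 -> 3 -> 4 (lag 2 samples, gain 0.6).
# Sized for a quick desk run; see the methods vignette for full-scale settings.
condition: awake
seed: 1
laplacian: true
selection: null        # skip the c_f grid search; use fixed_nm
fixed_nm: [4, 2]
train:
  corruption_fraction: 0.5
  learning_rate: 1
  minibatch: 200
  epochs: 2
  seed: 1
gc:
  p_max: 6
  n_perm: 99
  alpha: 0.05
input:
  type: synthetic
  spec:
    duration: 20
    seed: 1
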