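out_dir: "octnorm_demo_out"
groups: ["WT", "3xTg-AD"]
ages: [1, 4]
n_animals: 4
dims: [35, 35, 256]
noise: "speckle"
segmentation: "oracle"
pool_eyes: true
bonferroni_m: 8
seed: 1
qc:
  w: 3
  c_min: 0.05
  J: 15
  z_star: 4
  block_exclusion_frac: 0.10
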