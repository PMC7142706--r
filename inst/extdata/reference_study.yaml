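# Reference sampling-validity study: the packaged 636-pig herd and the five
# standard designs at 100,000 replicates. Only simple-random (S1) results and
# the sample-size facts are comparable with the source farm's published
# numbers: the pen-level placement of affected animals on that farm was never
# published, so the pen-based designs (S2-S5) are simulated here under the
# documented uniform-placement default.
herd:
  room_sizes: [88, 174, 174, 200]
  pens_per_room: 8
  max_pen_size: 25
  indicator_counts:
    tail_lesions: 20
    faecal_soiling: 28
    skin_lesions: 35
    ear_lesions: 54
    lameness: 37
    runts: 7
  clustering: 0
  seed: 1
strategies:
  S1: {kind: S1_simple, n_animals: 167}
  S2: {kind: S2_stratified, n_animals: 167}
  S3: {kind: S3_clustered, n_pens: 8}
  S4: {kind: S4_stratified_clustered, pens_per_stratum: 2}
  S5: {kind: S5_ktbl, ktbl_pens: 10, per_pen_cap: 15}
n_replicates: 100000
master_seed: 1
thresholds: [0.10, 0.30, 0.50]
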