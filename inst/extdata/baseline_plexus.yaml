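root_dimensions:
  root:
  - C5
  - C6
  - C7
  - C8
  - T1
  d_cranial_caudal:
  - 3.0
  - 3.1
  - 3.8
  - 2.7
  - 2.5
  d_transverse:
  - 1.1
  - 1.3
  - 1.6
  - 1.4
  - 1.4
  len_spinal_to_drg:
  - 7.5
  - 7.5
  - 7.5
  - 7.5
  - 7.5
  len_drg_to_foramen:
  - 9.0
  - 8.0
  - 7.0
  - 5.5
  - .na.real
  len_foramen_to_trunk:
  - 14.0
  - 15.5
  - 19.0
  - 7.0
  - 6.0
cord:
  width: 7.0
  attachment_y:
    C5: 4.3
    C6: 8.8
    C7: 13.5
    C8: 19.6
    T1: 26.2
  length: 30.2
angles:
  C5: 73.85
  C6: 77.4
  C7: 50.0
  C8: 37.5
  T1: 49.0
trunk_lengths:
  upper: 10.9
  middle: 4.8
  lower: 10.8
middle_trunk_kink: 31.0
load_cases:
- case1
- case2
mesh:
  h_max: 2.0
  h_min: 0.2
seed: 20240514
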