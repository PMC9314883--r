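tissues:
- name: background
  sigma: 0.0
  eps_r: 1.0
  rho: 0.0
- name: internal_air
  sigma: 0.0
  eps_r: 1.0
  rho: 1.2
- name: bone
  sigma: 0.083
  eps_r: 13.4
  rho: 1908.0
- name: muscle
  sigma: 0.77
  eps_r: 58.2
  rho: 1090.0
- name: fat
  sigma: 0.037
  eps_r: 5.6
  rho: 911.0
- name: white_matter
  sigma: 0.413
  eps_r: 43.8
  rho: 1041.0
- name: gray_matter
  sigma: 0.692
  eps_r: 60.0
  rho: 1045.0
- name: csf
  sigma: 2.224
  eps_r: 72.7
  rho: 1007.0
- name: eye
  sigma: 1.517
  eps_r: 69.0
  rho: 1005.0
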