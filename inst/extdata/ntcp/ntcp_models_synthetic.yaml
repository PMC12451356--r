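models:
- id: xerostomia_geq2
  endpoint: xerostomia
  grade: '>=2'
  intercept: -2.3
  terms:
  - structures:
    - parotid_l
    - parotid_r
    transform: sqrt
    coef: 0.33
- id: xerostomia_geq3
  endpoint: xerostomia
  grade: '>=3'
  intercept: -3.7
  terms:
  - structures:
    - parotid_l
    - parotid_r
    transform: sqrt
    coef: 0.3
- id: dysphagia_geq2
  endpoint: dysphagia
  grade: '>=2'
  intercept: -4.0
  terms:
  - structures:
    - oral_cavity
    transform: linear
    coef: 0.03
  - structures:
    - pcm_superior
    transform: linear
    coef: 0.025
- id: dysphagia_geq3
  endpoint: dysphagia
  grade: '>=3'
  intercept: -6.2
  terms:
  - structures:
    - oral_cavity
    transform: linear
    coef: 0.03
  - structures:
    - pcm_superior
    transform: linear
    coef: 0.025
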