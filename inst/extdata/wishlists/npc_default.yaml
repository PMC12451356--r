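name: npc_default
slack: 1.03
constraints:
- structure: brainstem
  metric: max_dose
  bound: 54.0
  robust: yes
- structure: brainstem_surface
  metric: max_dose
  bound: 60.0
  robust: yes
- structure: spinal_cord
  metric: max_dose
  bound: 45.0
  robust: yes
- structure: spinal_cord_surface
  metric: max_dose
  bound: 50.0
  robust: yes
- structure: chiasm
  metric: max_dose
  bound: 55.0
  robust: yes
- structure: optic_nerve_l
  metric: max_dose
  bound: 55.0
  robust: yes
- structure: optic_nerve_r
  metric: max_dose
  bound: 55.0
  robust: yes
- structure: ctv_ring
  metric: max_dose
  bound: 77.0
  robust: no
- structure: ctv_ring
  metric: per_beam_max_dose
  bound: 47.0
  robust: no
objectives:
- priority: 1
  structure: ctv7000_opt
  type: mean_underdose
  goal: 65.8
  robust: yes
  sufficient: yes
- priority: 2
  structure: ctv5425_opt
  type: mean_underdose
  goal: 51.0
  robust: yes
  sufficient: yes
- priority: 3
  structure: ctv_ring
  type: max_dose
  goal: 74.9
  robust: no
  sufficient: yes
- priority: 4
  structure: brainstem+brainstem_surface
  type: max_dose
  goal: 0.0
  robust: yes
  sufficient: no
- priority: 5
  structure: chiasm+optic_nerve_l+optic_nerve_r
  type: max_dose
  goal: 0.0
  robust: yes
  sufficient: no
- priority: 6
  structure: parotid_l+parotid_r
  type: mean_dose
  goal: 0.0
  robust: no
  sufficient: no
- priority: 7
  structure: oral_cavity+pcm_superior
  type: mean_dose
  goal: 0.0
  robust: no
  sufficient: no
- priority: 8
  structure: body_minus_ctvs
  type: mean_dose
  goal: 0.0
  robust: no
  sufficient: no
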