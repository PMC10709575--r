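morphology:
  n_oblique: 14.0
  trunk_sections: 4.0
  comps_per_section: 4.0
  trunk_section_length: 100.0
  trunk_diams:
  - 3.0
  - 3.0
  - 2.5
  - 2.0
  neck_comps: 2
  neck_diam: 1.2
  soma_length: 20.0
  soma_diam: 20.0
  axon_comps: 2
  axon_length: 50.0
  axon_diam: 1.0
  oblique_length: 100.0
  oblique_diam: 1.0
  basal_length: 250.0
  basal_diam: 4.0
  axial_resistivity: 150.0
  capacitance: 1.0
  leak_conductance: 2.5e-05
  leak_reversal: -66.0
channels:
- channel: Na
  gbar_at_soma: 0.06
  linear_slope: 0.0
  regions:
  - soma
  - axon
  reversal: 55.0
  x_min: 0.0
  x_max: .inf
- channel: Na
  gbar_at_soma: 0.16
  linear_slope: 0.0
  regions: axon
  reversal: 55.0
  x_min: 0.0
  x_max: .inf
- channel: K_DR
  gbar_at_soma: 0.03
  linear_slope: 0.0
  regions:
  - soma
  - axon
  reversal: -77.0
  x_min: 0.0
  x_max: .inf
- channel: K_DR
  gbar_at_soma: 0.02
  linear_slope: 0.0
  regions:
  - trunk
  - basal
  reversal: -77.0
  x_min: 0.0
  x_max: .inf
- channel: K_DR
  gbar_at_soma: 0.01
  linear_slope: 0.0
  regions: oblique
  reversal: -77.0
  x_min: 0.0
  x_max: .inf
- channel: K_A_proximal
  gbar_at_soma: 0.05
  linear_slope: 2.0e-05
  regions:
  - soma
  - trunk
  - basal
  reversal: -77.0
  x_min: 0.0
  x_max: 100.0
- channel: K_A_distal
  gbar_at_soma: 0.05
  linear_slope: 2.0e-05
  regions: trunk
  reversal: -77.0
  x_min: 100.0
  x_max: .inf
- channel: K_A_distal
  gbar_at_soma: 0.01
  linear_slope: 2.0e-05
  regions: oblique
  reversal: -77.0
  x_min: 0.0
  x_max: .inf
- channel: I_h
  gbar_at_soma: 0.0001
  linear_slope: 1.5e-06
  regions:
  - soma
  - trunk
  - oblique
  - basal
  reversal: -30.0
  x_min: 0.0
  x_max: .inf
- channel: K_M
  gbar_at_soma: 0.015
  linear_slope: 0.0
  regions:
  - soma
  - axon
  reversal: -77.0
  x_min: 0.0
  x_max: .inf
kinetics:
  na_m_half: -44.0
  na_m_slope: 5.5
  na_m_tau: 0.1
  na_h_half: -45.0
  na_h_slope: -4.0
  na_h_tau_half: -45.0
  na_h_tau_slope: 7.0
  na_h_tau_base: 1.0
  na_h_tau_amp: 8.0
  kdr_n_half: -20.0
  kdr_n_slope: 7.0
  kdr_n_tau: 2.5
  ka_a_half: -35.0
  ka_a_slope: 6.0
  ka_a_tau: 0.2
  ka_dist_shift: 0.0
  ka_b_half: -60.0
  ka_b_slope: -8.0
  ka_b_tau: 80.0
  ih_q_half: -82.0
  ih_q_slope: -7.0
  ih_q_tau: 50.0
  km_u_half: -30.0
  km_u_slope: 6.0
  km_u_tau: 40.0
  e_na: 55.0
  e_k: -77.0
  e_h: -30.0
synapse:
  ampa_rise: 0.5
  ampa_decay: 1.0
  nmda_rise: 5.0
  nmda_decay: 65.0
  reversal: 0.0
  mg_concentration: 1.0
  mg_eta: 1.0
  mg_gamma: 0.09
  nmda_to_ampa_ratio: 2.0
  ampa_saturation: 1.0
  nmda_saturation: 1.0
  g_max_factor: 3.0
  calibration_threshold: -22.0
stdp:
  M: -24.0
  V: 6.32
  tau: 2.0
  d: 0.3
  p: 1.0
  dendritic_spike_threshold: -10.0
integration:
  dt: 0.025
  dt_max: 0.05
  soma_spike_threshold: 0.0
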