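# Worked-example run configuration: a conical whisker with intrinsic
# parabolic curvature pushed against a thin pole in the concave-backward
# direction. All physical quantities carry their unit in the key name.
whisker:
  L_w_mm: 20
  r_base_um: 30
  r_tip_um: 1.5
  E_GPa: 3
  A_per_mm: 0.02
  x_vertex_mm: 0
pole:
  r_mm: 0.25
  x_mm: 15.13
  y_mm: 4.29
base:
  x_mm: 0
  y_mm: 0
  theta0_deg: 0
solve:
  theta_p_deg: 10
sweep:
  f_hz: 0.2
  amplitude_pp_deg: 30
  frame_rate: 32
  waveform: sine
detach_curve:
  d_mm: [10, 13, 15.66]
  directions: [CB]
seed: 1
output_dir: vibrissa_out
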