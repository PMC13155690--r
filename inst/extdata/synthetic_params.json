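{
  "_comment": "Synthetic sampling ranges for simulated participants. Package choices of realistic degree-scale values for this paradigm; not fitted values of any human participant.",
  "sigma0_v": [0.6, 1.8],
  "k1_v": [2.0, 6.0],
  "k2_v": [0.15, 0.5],
  "sigma0_a": [2.0, 5.0],
  "k1_a": [2.0, 6.0],
  "k2_a": [0.1, 0.4],
  "sigma_s": [6.0, 14.0],
  "sigma_delta": [6.0, 20.0],
  "b": [1.5, 4.0],
  "omega": [0.35, 0.75],
  "alpha_med": [1.4, 2.6],
  "alpha_low": [2.8, 5.0],
  "lambda": [0.01, 0.12],
  "sigma_motor": [0.4, 1.5],
  "rho_a": [1.15, 1.5],
  "p_same": [0.4, 0.7],
  "beta_v": [1.0, 1.35],
  "beta_a": [1.3, 1.9],
  "gamma": [0.8, 1.25],
  "theta_v_base": [-0.4, 0.5],
  "theta_v": [-4.0, -1.0],
  "theta_a_base": [0.7, 1.6],
  "theta_a": [-4.0, -1.0],
  "theta_p": [-3.0, -0.5]
}
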