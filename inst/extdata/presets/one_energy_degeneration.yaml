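# Degeneration-driven collapse: identical to one_energy_homeostasis until
# t0_degen, when the hyperparasite's catalytic rate starts decaying
# exponentially (half-time ln(2)/d ~ 139, fast against the ~500-unit
# energy cycle). Once gamma*Y falls below alpha*H + beta*X the energy
# balance turns permanently negative: after the final switch to full
# virulence E declines monotonically to 0 and the unit disintegrates.
name: one_energy_degeneration
model: one_energy
habitat: {H: 4.0, kappa: 2.0, sigma: 1.0, q: 2.0}
pair: {a1: 1.0, a0: 1.0, b1: 1.0, b0: 1.0}
energy: {alpha: 0.001, beta: 0.002, gamma: 0.01, d: 5.0e-3, t0_degen: 2.0e+4}
relay: {E_lower: 1.0, E_upper: 2.0}
init: {X1: 4.0, Y1: 1.6, E1: 1.5}
integrator: {t_end: 9.0e+4, rel_tol: 1.0e-8, abs_tol: 1.0e-10, sample_dt: 10.0}
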