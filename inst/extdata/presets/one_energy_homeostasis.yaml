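# Sustained one-energy homeostasis: the hyperparasite catalyses enough
# operating energy during virulent phases to keep E cycling inside the
# relay band indefinitely. Populations start at the analytic equilibrium
# (with H = 4 it is reached quickly in any case), so the energy trace is
# confined to [E_lower, E_upper] after the first switch.
name: one_energy_homeostasis
model: one_energy
habitat: {H: 4.0, kappa: 2.0, sigma: 1.0, q: 2.0}
pair: {a1: 1.0, a0: 1.0, b1: 1.0, b0: 1.0}
# equilibrium: X = 4, Y = 1.6; during virulent phases
# dE = gamma*Y - alpha*H - beta*X = 0.016 - 0.004 - 0.008 = +0.004
energy: {alpha: 0.001, beta: 0.002, gamma: 0.01, d: 0.0, t0_degen: .inf}
relay: {E_lower: 1.0, E_upper: 2.0}
init: {X1: 4.0, Y1: 1.6, E1: 1.5}
integrator: {t_end: 9.0e+4, rel_tol: 1.0e-8, abs_tol: 1.0e-10, sample_dt: 10.0}
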