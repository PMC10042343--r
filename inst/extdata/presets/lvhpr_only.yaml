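# Plain host-nested pair at full virulence: damped oscillation into the
# coexistence equilibrium (X = 4, Y = 1.6 at H = 4), starting from half
# the equilibrium loads. Sweeping habitat.H shows the equilibria scaling
# linearly with the host population.
name: lvhpr_only
model: lvhpr_only
habitat: {H: 4.0, kappa: 2.0, sigma: 1.0, q: 2.0}
pair: {a1: 1.0, a0: 1.0, b1: 1.0, b0: 1.0}
v: 1.0
init: {X1: 2.0, Y1: 0.8}
integrator: {t_end: 1.0e+5, rel_tol: 1.0e-8, abs_tol: 1.0e-10, sample_dt: 10.0}
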