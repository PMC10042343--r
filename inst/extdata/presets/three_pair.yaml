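# Two energies, three pairs: the full catalytic life cycle. Pair 1
# (E1-gated) transforms stored energy E2 into operating energy E1; pair 2
# (E2-gated) catalyses fresh E1; pair 3 (E2-gated) converts E1 back into
# E2 at ratio theta. The E2 relay band recharges in short bursts, so the
# vE2 virulence phases are brief compared with vE1. Populations start off
# equilibrium (joint equilibrium: X_k = 4, Y_k = 1.6) and converge to it.
name: three_pair
model: two_energy_three_pair
habitat: {H: 4.0, kappa: 6.0, sigma: 1.0, q: 2.0}
pairs:
  - {a1: 1.0, a0: 1.0, b1: 1.0, b0: 1.0}
  - {a1: 1.0, a0: 1.0, b1: 1.0, b0: 1.0}
  - {a1: 1.0, a0: 1.0, b1: 1.0, b0: 1.0}
energy:
  alpha1: 1.0e-3   # E1 drain per host
  alpha2: 2.0e-5   # isolation-material decay
  gamma1: 1.0e-3   # E2 -> E1 via Y1 (enters E1 as gamma1/theta)
  gamma2: 0.15     # de-novo E1 catalysis via Y2
  gamma3: 0.125    # E1 -> E2 via Y3 (enters E2 as gamma3*theta)
  theta: 0.1
relay_E1: {E_lower: 1.0, E_upper: 2.0}
relay_E2: {E_lower: 0.5, E_upper: 1.5}
init: {X1: 2.0, Y1: 1.0, X2: 2.0, Y2: 1.0, X3: 2.0, Y3: 1.0, E1: 1.5, E2: 1.0}
integrator: {t_end: 1.0e+6, rel_tol: 1.0e-8, abs_tol: 1.0e-10, sample_dt: 100.0}
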