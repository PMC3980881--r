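# Reduced-model energy parameters (version 1).
#
# Surrogate parameterization with ECEPP-family functional forms over the
# reduced atom set (backbone N/CA/C/O, CB, generic side-chain pseudo-atoms
# X). Units: Angstrom, kcal/mol, degrees, elementary charges. These
# constants define the package's own energy surface; they are not a
# published force field.
version: 1
dielectric: 2.0
coulomb_k: 332.0
lj:               # per-class Lennard-Jones: rmin (A), eps (kcal/mol)
  "N": {rmin: 3.40, eps: 0.160}
  CA: {rmin: 4.00, eps: 0.100}
  C:  {rmin: 3.90, eps: 0.105}
  O:  {rmin: 3.20, eps: 0.200}
  CB: {rmin: 4.00, eps: 0.120}
  X:  {rmin: 4.10, eps: 0.120}
charge:           # partial charges (e)
  "N": -0.30
  CA: 0.05
  C:  0.40
  O: -0.40
  CB: 0.05
  X:  0.00
hbond:            # 12-10 donor(N)-acceptor(O) potential: A/r^12 - B/r^10
  A: 3.538e+6      # minimum near 2.9 A, depth ~2 kcal/mol
  B: 5.048e+5
torsion:          # (U0/2) * (1 + cos(n * theta - theta0))
  phi:   {U0: 1.0,  "n": 3, theta0: 0}
  psi:   {U0: 1.0,  "n": 3, theta0: 0}
  omega: {U0: 20.0, "n": 2, theta0: 180}
  chi:   {U0: 2.8,  "n": 3, theta0: 0}
clash_r_min: 1.0e-06  # pair-distance floor (A)
clash_penalty: 1.0e+10 # finite energy charged to sub-floor pairs
repulsion_cap: 1.0e+4 # soft-core saturation of the 12-power repulsion

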