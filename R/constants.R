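# Physical constants (CODATA 2018) in the unit system used throughout:
# energies kcal/mol, entropies cal/(mol K), lengths Angstrom, charges e,
# time ps/ns, temperature K, pressure atm.

.const <- list(
  planck     = 6.62607015e-34,    # J s
  boltzmann  = 1.380649e-23,      # J/K
  avogadro   = 6.02214076e23,     # 1/mol
  c_cm       = 2.99792458e10,     # speed of light, cm/s
  amu_kg     = 1.66053906892e-27, # kg
  cal_joule  = 4.184,             # J per thermochemical calorie
  atm_pa     = 101325,            # Pa
  # Amber electrostatic constant: k_e in kcal A / (mol e^2)
  coulomb_k  = 332.0637
)

# Gas constant in cal/(mol K) and kcal/(mol K)
.const$R_cal  <- .const$boltzmann * .const$avogadro / .const$cal_joule
.const$R_kcal <- .const$R_cal / 1000
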