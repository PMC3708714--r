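# Fixed physical parameters of the CI / P_RM thermodynamic model.
# Free energies in kcal/mol at 25 C (RT = 0.593 kcal/mol).
#
# Intrinsic dimer-operator binding and adjacent-pair cooperativity values
# are the standard equilibrium constants for the lambda operators from the
# quantitative-footprinting literature; they are deliberately editable so
# alternative fixed-parameter sets can be swapped in without touching code.
binding:
  OL1: -12.5
  OL2: -10.5
  OL3: -9.7
  OR1: -12.5
  OR2: -10.5
  OR3: -9.5
# single adjacent-pair cooperativity (applies to OL12, OL23, OR12, OR23)
cooperativity: -3.0
RT: 0.593
# wild-type lysogenic CI concentration (monomer equivalents) and the
# molecules/cell <-> nM conversion for a typical E. coli cell volume
ci_wt_nM: 220.0
nM_per_molecule: 1.47
# fraction of total CI present as free dimers (the remainder is
# nonspecifically bound to chromosomal DNA or monomeric); fixed at its
# value for ~150 molecules/cell
phi_dimer: 0.1
# CI degradation/dilution rate: half-life equal to the 2-h doubling time
doubling_time_min: 120.0
# basal P_RM rate as a fraction of R_unloop (weak unactivated transcription)
R_basal_frac: 0.2
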