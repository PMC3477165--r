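# Minimal self-consistent MM parameter set for the synthetic test systems.
# Units: mass amu, sigma nm, eps kJ/mol, charge e, K_r kJ/mol/nm^2,
# K_theta kJ/mol/rad^2, K_phi kJ/mol, r0 nm, angles in degrees.

# atom types
ATOM CAP 12.011 0.350 0.30 0.0
ATOM CBP 12.011 0.350 0.30 0.0
ATOM OW  15.999 0.31656 0.65017 -0.82
ATOM HW  1.008  0.0     0.0      0.41
ATOM LC  12.011 0.330 0.35 0.0

# name -> type ('*' matches any protein residue)
TYPEMAP *   CA  CAP
TYPEMAP *   CB  CBP
TYPEMAP SOL OW  OW
TYPEMAP SOL HW1 HW
TYPEMAP SOL HW2 HW
TYPEMAP LIG C1  LC
TYPEMAP LIG C2  LC
TYPEMAP LIG C3  LC
TYPEMAP LIG C4  LC
TYPEMAP LIG C5  LC

# SPC water geometry (K = 0: rigid, maintained by SHAKE on H-bonds)
BOND SOL OW  HW1 0 0.1
BOND SOL OW  HW2 0 0.1
BOND SOL HW1 HW2 0 0.16330

# pseudo side chain
BOND * CA CB 20000 0.153

# toy ligand chain
BOND LIG C1 C2 20000 0.15
BOND LIG C2 C3 20000 0.15
BOND LIG C3 C4 20000 0.15
BOND LIG C4 C5 20000 0.15
ANGLE LIG C1 C2 C3 400 109.47
ANGLE LIG C2 C3 C4 400 109.47
ANGLE LIG C3 C4 C5 400 109.47
DIHEDRAL LIG C1 C2 C3 C4 5 3 0
DIHEDRAL LIG C2 C3 C4 C5 5 3 0

# pseudo-backbone bond between consecutive atomistic protein residues
BACKBONE CA CA 20000 0.38
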