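# Default parameterization of bilayer-MscL interactions.
# All energies in kBT, lengths in nm, tensions in kBT/nm^2.
material:
  Kb_kt: 20.0                # bilayer bending rigidity
  Kt_kt_per_nm2: 60.0        # thickness-deformation stiffness (strain u/l)
  tau_kt_per_nm2: 0.0        # membrane tension (energy scans use 0)
temperature_K: 298
states:
  r_closed_nm: 2.5           # cylinder-model radius, closed state
  r_open_nm: 3.5             # cylinder-model radius, open state
thickness:
  # equal-thickness model: one protein hydrophobic thickness for both
  # states, matching the hydrophobic thickness of a PC12 bilayer
  W_equal_nm: 1.925
  # distinct-thickness model: crystallographic closed state, modeled open
  W_closed_nm: 2.5
  W_open_nm: 2.1
tail_map:
  # fluid-PC calibration: 2l = 0.175 * (n_carbons - 1) nm
  slope_nm_per_carbon: 0.175
  intercept_nm: -0.175
reference_lipid_n_carbons: 18
shapes:
  polygon_max_multiple: 3
  cloverleaf:
    closed_pentamer_eps: 0.22   # fitted lobe amplitude, closed pentamer
    open_pentamer_eps: 0.13     # fitted lobe amplitude, open pentamer
    hexamer_eps: 0.12           # fitted lobe amplitude, both hexamer states
  systematic:
    closed_eps: 0.20            # model scans: equal absolute lobe amplitude
    # open-state eps is closed_eps * r_closed/r_open so R0*eps matches
validity_threshold: 0.35
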