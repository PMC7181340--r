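# Expected pipeline outputs for the bundled petunidin fixture, with the
# tolerances at which they are asserted. Entries under `synthetic` have no
# published anchor and were chosen once as field-realistic values.
molecule: petunidin
smiles: "COc1cc(-c2[o+]c3cc(O)cc(O)c3cc2O)cc(O)c1O"
references:
  gas:
    # H(H.) back-solved so the printed cycle sum AIP+PDE = PA+ETE = 392.47
    # kcal/mol closes exactly; H(H+) = 2.5RT, H(e-) literature convention
    proton: 0.00236
    electron: 0.00120
    h_atom_rule: "proton - 313.75 kcal/mol"
expected:
  site_thermo_gas:
    bde: {"3": 78.72, "5": 85.06, "7": 88.94, "3'": 90.25, "4'": 79.84}
    aip: 229.91
    pde_site3: 162.56
    pa_site3: -112.68
    ete_site3: 505.15
    cycle_sum: 392.47
    tolerance_kcal_mol: 1.0e-9
  site_thermo_water:
    bde_site3: 77.02
    tolerance_kcal_mol: 1.0e-9
  bde_ordering: "3 < 4' < 5 < 7 < 3'"
  preferred_mechanism_gas: HAT
  descriptors_energy_method:
    eta: 2.55
    chi: 7.42
    mu: -7.42
    tolerance: 0.005       # 2-decimal reporting
  optical:
    gap_ev: 2.57
    wavelength_nm: 483
    tolerance_nm: 1
  structure_counts:
    heavy_atoms: 23
    mw: 317.27
    hbd: 5
    hba: 7
    rotb: 2
    tpsa: 121.54
    tpsa_tolerance: 2.5    # charged aromatic O fragment unpublished
  druglikeness:
    lipinski_violations: 0
    veber_pass: true
    drug_score: 0.804
    drug_score_tolerance: 0.005
  site_concordance: 1.0
  substituent_effect:
    amino: all_lower
    glucoside: all_lower   # site 3 glycosylated, 4 comparable sites
synthetic:
  - aqueous reference enthalpies (nominal hydration shifts)
  - aqueous BDE at sites 5/7/3'/4' (gas spacing preserved)
  - per-site PA beyond site 3 (3 kcal/mol spacing in pKa order)
  - aqueous AIP and PA regime
  - atomic charges beyond site 3
table6_columns: "A = parent, B = amino variant, C = 3-glucoside ('-' at site 3)"
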