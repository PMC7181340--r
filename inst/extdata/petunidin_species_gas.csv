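"molecule_id","form","site","phase","enthalpy_hartree","electronic_energy_hartree","homo_ev","lumo_ev"
"petunidin","neutral","","gas","-1143.8800000000001","-1143.8800000000001","-8.7300000000000004","-6.1600000000000001"
"petunidin","radical","3","gas","-1143.2569192696208","","",""
"petunidin","radical","5","gas","-1143.2468158369238","","",""
"petunidin","radical","7","gas","-1143.2406326636012","","",""
"petunidin","radical","3'","gas","-1143.2385450458044","","",""
"petunidin","radical","4'","gas","-1143.2551344360845","","",""
"petunidin","radical_cation","","gas","-1143.513615108616","","",""
"petunidin","anion","3","gas","-1144.0619270025713","","",""
"petunidin","anion","5","gas","-1144.0571461984559","","",""
"petunidin","anion","7","gas","-1144.0523653943408","","",""
"petunidin","anion","3'","gas","-1144.0475845902254","","",""
"petunidin","anion","4'","gas","-1144.04280378611","","",""
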