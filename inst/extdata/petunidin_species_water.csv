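"molecule_id","form","site","phase","enthalpy_hartree","electronic_energy_hartree","homo_ev","lumo_ev"
"petunidin","neutral","","water","-1143.9000000000001","","-8.8000000000000007","-6.0899999999999999"
"petunidin","radical","3","water","-1143.2772379898952","","",""
"petunidin","radical","5","water","-1143.267134557198","","",""
"petunidin","radical","7","water","-1143.2609513838756","","",""
"petunidin","radical","3'","water","-1143.2588637660785","","",""
"petunidin","radical","4'","water","-1143.2754531563587","","",""
"petunidin","radical_cation","","water","-1143.676895807952","","",""
"petunidin","anion","3","water","-1143.4308133540928","","",""
"petunidin","anion","5","water","-1143.4260325499774","","",""
"petunidin","anion","7","water","-1143.421251745862","","",""
"petunidin","anion","3'","water","-1143.4164709417469","","",""
"petunidin","anion","4'","water","-1143.4116901376315","","",""
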