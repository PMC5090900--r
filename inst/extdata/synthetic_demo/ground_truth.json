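{
  "planted": [
    {
      "position": 2,
      "ingroup_residue": "P",
      "outgroup_residues": "CF"
    },
    {
      "position": 29,
      "ingroup_residue": "Q",
      "outgroup_residues": "YK"
    },
    {
      "position": 38,
      "ingroup_residue": "I",
      "outgroup_residues": "YK"
    },
    {
      "position": 41,
      "ingroup_residue": "V",
      "outgroup_residues": "FQ"
    },
    {
      "position": 45,
      "ingroup_residue": "Y",
      "outgroup_residues": "FL"
    },
    {
      "position": 62,
      "ingroup_residue": "K",
      "outgroup_residues": "WT"
    },
    {
      "position": 63,
      "ingroup_residue": "T",
      "outgroup_residues": "A"
    },
    {
      "position": 67,
      "ingroup_residue": "G",
      "outgroup_residues": "C"
    },
    {
      "position": 94,
      "ingroup_residue": "I",
      "outgroup_residues": "MH"
    },
    {
      "position": 98,
      "ingroup_residue": "Y",
      "outgroup_residues": "CA"
    },
    {
      "position": 107,
      "ingroup_residue": "F",
      "outgroup_residues": "IY"
    }
  ],
  "ingroup_ids": ["marine1", "marine2"],
  "variants": [
    {
      "variant_id": "marine1",
      "habitat": "marine",
      "true_activity": 1,
      "true_expression": 1,
      "true_solubility": 0.4,
      "detected": true
    },
    {
      "variant_id": "marine2",
      "habitat": "marine",
      "true_activity": 0.229872171813854,
      "true_expression": 0.391206920161628,
      "true_solubility": 0.26374432874145,
      "detected": true
    },
    {
      "variant_id": "fresh1",
      "habitat": "freshwater",
      "true_activity": 0.7177342405691,
      "true_expression": 0.490766726720187,
      "true_solubility": 0.2596189003787,
      "detected": true
    },
    {
      "variant_id": "fresh2",
      "habitat": "freshwater",
      "true_activity": 2.0122059330605,
      "true_expression": 0.477389183251291,
      "true_solubility": 0.459497636265587,
      "detected": true
    },
    {
      "variant_id": "fresh3",
      "habitat": "freshwater",
      "true_activity": 1.91939163918889,
      "true_expression": 3.35640184111286,
      "true_solubility": 0.343148552230559,
      "detected": true
    },
    {
      "variant_id": "fresh4",
      "habitat": "freshwater",
      "true_activity": 0.886602625438075,
      "true_expression": 1.25487088605243,
      "true_solubility": 0.166029023681767,
      "detected": true
    },
    {
      "variant_id": "fresh5",
      "habitat": "freshwater",
      "true_activity": 0.291859851313877,
      "true_expression": 0.936521718093781,
      "true_solubility": 0.317097649665084,
      "detected": true
    },
    {
      "variant_id": "fresh6",
      "habitat": "freshwater",
      "true_activity": 2.49252367638123,
      "true_expression": 0.639921062909722,
      "true_solubility": 0.0671892660902813,
      "detected": true
    }
  ]
}
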