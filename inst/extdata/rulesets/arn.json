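{
  "disease_id": "arn",
  "disease_name": "Acute retinal necrosis",
  "anatomic_class": "infectious_post_pan",
  "provenance": "SUN Working Group consensus classification criteria, infectious posterior uveitis/panuveitis stratum.",
  "criteria": {
    "and": [
      {
        "comment": "Item 1: necrotizing retinitis involving the peripheral retina",
        "finding_is": {"code": "necrotizing_retinitis_peripheral", "value": "present"}
      },
      {
        "comment": "AND (either Item 2 OR Item 3)",
        "or": [
          {
            "comment": "Item 2: evidence of infection with either HSV or VZV - positive PCR from an aqueous or vitreous specimen",
            "or": [
              {"test_is": {"code": "pcr_aqueous_hsv", "value": "positive"}},
              {"test_is": {"code": "pcr_aqueous_vzv", "value": "positive"}},
              {"test_is": {"code": "pcr_vitreous_hsv", "value": "positive"}},
              {"test_is": {"code": "pcr_vitreous_vzv", "value": "positive"}}
            ]
          },
          {
            "comment": "Item 3: characteristic clinical picture - circumferential or confluent retinitis AND retinal vascular sheathing and/or occlusion AND more than minimal vitritis",
            "and": [
              {"finding_is": {"code": "confluent_retinitis", "value": "present"}},
              {"finding_is": {"code": "retinal_vascular_sheathing_or_occlusion", "value": "present"}},
              {"finding_is": {"code": "more_than_minimal_vitritis", "value": "present"}}
            ]
          }
        ]
      }
    ]
  },
  "exclusions": [
    {
      "comment": "Exclusion 1: positive syphilis serology with a treponemal test",
      "test_is": {"code": "syphilis_serology_treponemal", "value": "positive"}
    },
    {
      "comment": "Exclusion 2: intraocular specimen PCR-positive for CMV or Toxoplasma gondii, unless the host is immunocompromised, there is morphologic evidence of more than one infection, the characteristic clinical picture of acute retinal necrosis is present, and the intraocular specimen is PCR-positive for either HSV or VZV",
      "and": [
        {"or": [
          {"test_is": {"code": "pcr_intraocular_cmv", "value": "positive"}},
          {"test_is": {"code": "pcr_intraocular_toxoplasma", "value": "positive"}}
        ]},
        {"not": {
          "and": [
            {"test_is": {"code": "immunocompromised", "value": "positive"}},
            {"finding_is": {"code": "morphologic_evidence_multiple_infections", "value": "present"}},
            {"finding_is": {"code": "confluent_retinitis", "value": "present"}},
            {"finding_is": {"code": "retinal_vascular_sheathing_or_occlusion", "value": "present"}},
            {"finding_is": {"code": "more_than_minimal_vitritis", "value": "present"}},
            {"or": [
              {"test_is": {"code": "pcr_intraocular_hsv", "value": "positive"}},
              {"test_is": {"code": "pcr_intraocular_vzv", "value": "positive"}}
            ]}
          ]
        }}
      ]
    }
  ]
}
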