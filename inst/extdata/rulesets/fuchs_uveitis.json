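{
  "disease_id": "fuchs_uveitis",
  "disease_name": "Fuchs uveitis syndrome",
  "anatomic_class": "anterior",
  "provenance": "SUN Working Group consensus classification criteria, anterior uveitis stratum.",
  "criteria": {
    "and": [
      {
        "comment": "Item 1: evidence of anterior uveitis - anterior chamber cells; if vitreous cells are present, anterior chamber inflammation should also be present; no evidence of active retinitis",
        "and": [
          {"finding_is": {"code": "anterior_chamber_cells", "value": "present"}},
          {"or": [
            {"finding_is": {"code": "vitreous_cells_anterior", "value": "absent"}},
            {"finding_is": {"code": "anterior_chamber_cells", "value": "present"}}
          ]},
          {"finding_is": {"code": "active_retinitis", "value": "absent"}}
        ]
      },
      {
        "comment": "Item 2: unilateral uveitis",
        "laterality_in": ["unilateral"]
      },
      {
        "comment": "Item 3: signs of Fuchs uveitis syndrome - heterochromia OR (unilateral diffuse iris atrophy AND stellate keratic precipitates)",
        "or": [
          {"finding_is": {"code": "heterochromia", "value": "present"}},
          {"and": [
            {"finding_is": {"code": "diffuse_iris_atrophy", "value": "present"}},
            {"finding_is": {"code": "stellate_keratic_precipitates", "value": "present"}}
          ]}
        ]
      },
      {
        "comment": "Item 4: neither endotheliitis nor nodular coin-shaped endothelial lesions",
        "and": [
          {"finding_is": {"code": "endotheliitis", "value": "absent"}},
          {"finding_is": {"code": "coin_shaped_endothelial_lesions", "value": "absent"}}
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
      "comment": "Exclusion 2: evidence of sarcoidosis - bilateral hilar adenopathy on chest imaging or tissue biopsy with noncaseating granulomas",
      "or": [
        {"test_is": {"code": "chest_xray_bilateral_hilar_adenopathy", "value": "positive"}},
        {"test_is": {"code": "biopsy_noncaseating_granulomas", "value": "positive"}}
      ]
    },
    {
      "comment": "Exclusion 3: aqueous specimen PCR-positive for CMV, HSV or VZV",
      "or": [
        {"test_is": {"code": "pcr_aqueous_cmv", "value": "positive"}},
        {"test_is": {"code": "pcr_aqueous_hsv", "value": "positive"}},
        {"test_is": {"code": "pcr_aqueous_vzv", "value": "positive"}}
      ]
    }
  ]
}
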