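{
  "disease_id": "spa_hla_b27",
  "disease_name": "Spondyloarthritis/HLA-B27-associated anterior uveitis",
  "anatomic_class": "anterior",
  "provenance": "SUN Working Group consensus classification criteria, anterior uveitis stratum.",
  "criteria": {
    "and": [
      {
        "comment": "Item 1: evidence of anterior uveitis - anterior chamber cells; if anterior vitreous cells are present their severity is lower than the anterior chamber inflammation",
        "and": [
          {"finding_is": {"code": "anterior_chamber_cells", "value": "present"}},
          {"or": [
            {"finding_is": {"code": "vitreous_cells_anterior", "value": "absent"}},
            {"grade_lt": {"code": "vitreous_cells_anterior", "than": "anterior_chamber_cells"}}
          ]}
        ]
      },
      {
        "or": [
          {
            "comment": "(Item 2 AND Item 3)",
            "and": [
              {
                "comment": "Item 2: characteristic uveitis course",
                "or": [
                  {
                    "comment": "2a: acute or recurrent acute, unilateral or alternating unilateral course",
                    "and": [
                      {"course_in": ["acute", "recurrent_acute"]},
                      {"laterality_in": ["unilateral", "alternating_unilateral"]}
                    ]
                  },
                  {
                    "comment": "2b: chronic course with a history of recurrent acute episodes, unilateral or alternating, evolving into a chronic course",
                    "and": [
                      {"course_in": ["chronic_after_recurrent_acute"]},
                      {"laterality_in": ["unilateral", "alternating_unilateral"]}
                    ]
                  }
                ]
              },
              {
                "comment": "Item 3: ASAS-defined spondyloarthritis (axial or peripheral) and/or HLA-B27 positive",
                "or": [
                  {"test_is": {"code": "asas_spondyloarthritis", "value": "positive"}},
                  {"test_is": {"code": "hla_b27", "value": "positive"}}
                ]
              }
            ]
          },
          {
            "comment": "Alternative pathway: chronic uveitis with both ASAS-defined spondyloarthritis AND HLA-B27 positive",
            "and": [
              {"course_in": ["chronic", "chronic_after_recurrent_acute"]},
              {"test_is": {"code": "asas_spondyloarthritis", "value": "positive"}},
              {"test_is": {"code": "hla_b27", "value": "positive"}}
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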