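{
  "disease_id": "synthetic_viral_au",
  "disease_name": "SYNTHETIC viral anterior uveitis (test stand-in, not a published criteria set)",
  "anatomic_class": "anterior",
  "provenance": "Synthetic stand-in rule set used to exercise the derivation pipeline with a third anterior disease; its content is invented and must not be used clinically.",
  "criteria": {
    "and": [
      {"finding_is": {"code": "anterior_chamber_cells", "value": "present"}},
      {"laterality_in": ["unilateral"]},
      {
        "comment": "aqueous PCR positive for one of the herpes-family viruses",
        "or": [
          {"test_is": {"code": "pcr_aqueous_cmv", "value": "positive"}},
          {"test_is": {"code": "pcr_aqueous_hsv", "value": "positive"}},
          {"test_is": {"code": "pcr_aqueous_vzv", "value": "positive"}}
        ]
      }
    ]
  },
  "exclusions": [
    {
      "comment": "positive syphilis serology with a treponemal test",
      "test_is": {"code": "syphilis_serology_treponemal", "value": "positive"}
    },
    {
      "comment": "evidence of sarcoidosis",
      "or": [
        {"test_is": {"code": "chest_xray_bilateral_hilar_adenopathy", "value": "positive"}},
        {"test_is": {"code": "biopsy_noncaseating_granulomas", "value": "positive"}}
      ]
    }
  ]
}
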