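{
  "version": "0.1.0",
  "description": "Controlled vocabulary for uveitis case records: clinical findings (tri-state present/absent/unknown, some gradable 0-4) and laboratory/imaging test results (tri-state positive/negative/unknown). Extensible data file; ships the terms needed by the three bundled rule sets plus generic uveitis descriptors.",
  "findings": [
    {"code": "anterior_chamber_cells", "gradable": true, "label": "Anterior chamber cells"},
    {"code": "vitreous_cells_anterior", "gradable": true, "label": "Anterior vitreous cells"},
    {"code": "stellate_keratic_precipitates", "gradable": false, "label": "Stellate keratic precipitates"},
    {"code": "heterochromia", "gradable": false, "label": "Iris heterochromia"},
    {"code": "diffuse_iris_atrophy", "gradable": false, "label": "Unilateral diffuse iris atrophy"},
    {"code": "posterior_synechiae", "gradable": false, "label": "Posterior synechiae"},
    {"code": "endotheliitis", "gradable": false, "label": "Endotheliitis"},
    {"code": "coin_shaped_endothelial_lesions", "gradable": false, "label": "Nodular coin-shaped endothelial lesions"},
    {"code": "active_retinitis", "gradable": false, "label": "Active retinitis"},
    {"code": "necrotizing_retinitis_peripheral", "gradable": false, "label": "Necrotizing retinitis involving the peripheral retina"},
    {"code": "confluent_retinitis", "gradable": false, "label": "Circumferential or confluent retinitis"},
    {"code": "retinal_vascular_sheathing_or_occlusion", "gradable": false, "label": "Retinal vascular sheathing and/or occlusion"},
    {"code": "more_than_minimal_vitritis", "gradable": false, "label": "More than minimal vitritis"},
    {"code": "morphologic_evidence_multiple_infections", "gradable": false, "label": "Morphologic evidence of more than one intraocular infection"}
  ],
  "tests": [
    {"code": "hla_b27", "label": "HLA-B27"},
    {"code": "asas_spondyloarthritis", "label": "ASAS-defined spondyloarthritis (axial or peripheral)"},
    {"code": "syphilis_serology_treponemal", "label": "Syphilis serology, treponemal test"},
    {"code": "chest_xray_bilateral_hilar_adenopathy", "label": "Bilateral hilar adenopathy on chest imaging"},
    {"code": "biopsy_noncaseating_granulomas", "label": "Tissue biopsy with noncaseating granulomas"},
    {"code": "pcr_aqueous_cmv", "label": "Aqueous humor PCR, cytomegalovirus"},
    {"code": "pcr_aqueous_hsv", "label": "Aqueous humor PCR, herpes simplex virus"},
    {"code": "pcr_aqueous_vzv", "label": "Aqueous humor PCR, varicella zoster virus"},
    {"code": "pcr_vitreous_hsv", "label": "Vitreous PCR, herpes simplex virus"},
    {"code": "pcr_vitreous_vzv", "label": "Vitreous PCR, varicella zoster virus"},
    {"code": "pcr_intraocular_cmv", "label": "Intraocular specimen PCR, cytomegalovirus"},
    {"code": "pcr_intraocular_toxoplasma", "label": "Intraocular specimen PCR, Toxoplasma gondii"},
    {"code": "pcr_intraocular_hsv", "label": "Intraocular specimen PCR, herpes simplex virus"},
    {"code": "pcr_intraocular_vzv", "label": "Intraocular specimen PCR, varicella zoster virus"},
    {"code": "immunocompromised", "label": "Immunocompromised host"}
  ]
}
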