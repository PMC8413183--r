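# Clinical vignette fixtures: prototype cases that cleanly satisfy each
# shipped rule set, plus a mutator for deriving per-item variations.

negative_workup <- list(
  syphilis_serology_treponemal = "negative",
  chest_xray_bilateral_hilar_adenopathy = "negative",
  biopsy_noncaseating_granulomas = "negative",
  pcr_aqueous_cmv = "negative", pcr_aqueous_hsv = "negative",
  pcr_aqueous_vzv = "negative")

spa_base <- function() {
  uv_case("spa_vignette", "anterior", course = "recurrent_acute",
          laterality = "unilateral",
          findings = list(anterior_chamber_cells = list(value = "present", grade = 2),
                          vitreous_cells_anterior = "absent"),
          tests = c(list(hla_b27 = "positive", asas_spondyloarthritis = "negative"),
                    negative_workup))
}

fuchs_base <- function() {
  uv_case("fuchs_vignette", "anterior", laterality = "unilateral",
          findings = list(anterior_chamber_cells = list(value = "present", grade = 1),
                          vitreous_cells_anterior = "absent",
                          active_retinitis = "absent",
                          heterochromia = "present",
                          diffuse_iris_atrophy = "absent",
                          stellate_keratic_precipitates = "absent",
                          endotheliitis = "absent",
                          coin_shaped_endothelial_lesions = "absent"),
          tests = negative_workup)
}

arn_base <- function() {
  uv_case("arn_vignette", "infectious_post_pan",
          findings = list(necrotizing_retinitis_peripheral = "present"),
          tests = list(pcr_aqueous_hsv = "positive",
                       syphilis_serology_treponemal = "negative",
                       pcr_intraocular_cmv = "negative",
                       pcr_intraocular_toxoplasma = "negative"))
}

# Derive a vignette: `findings`/`tests` entries override or (value NULL /
# "unknown") remove fields of the base case.
vignette <- function(base, findings = list(), tests = list(), course = NULL,
                     laterality = NULL) {
  f <- base$findings
  for (code in names(findings)) {
    v <- findings[[code]]
    if (is.null(v) || identical(v, "unknown")) f[[code]] <- NULL
    else f[[code]] <- if (is.list(v)) v else list(value = v, grade = NULL)
  }
  t <- as.list(base$tests)
  for (code in names(tests)) {
    v <- tests[[code]]
    if (is.null(v) || identical(v, "unknown")) t[[code]] <- NULL else t[[code]] <- v
  }
  uv_case(base$case_id, base$anatomic_class,
          course = course %||% base$course,
          laterality = laterality %||% base$laterality,
          findings = f, tests = t, true_label = base$true_label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The vignette table: one row per asserted vignette, >= 2 per printed
# criteria item and exclusion item of the three shipped rule sets.
vignette_table <- function() {
  sp <- spa_base(); fu <- fuchs_base(); ar <- arn_base()
  v <- list()
  add <- function(id, case, disease, expect)
    v[[length(v) + 1L]] <<- list(id = id, case = case, disease = disease,
                                 expect = expect)

  ## --- SpA/HLA-B27 anterior uveitis -----------------------------------
  add("spa/1a+", sp, "spa_hla_b27", "classified")
  add("spa/1a-", vignette(sp, findings = list(anterior_chamber_cells = "absent")),
      "spa_hla_b27", "criteria_not_met")
  add("spa/1b+ vitreous less severe",
      vignette(sp, findings = list(vitreous_cells_anterior = list(value = "present", grade = 1))),
      "spa_hla_b27", "classified")
  add("spa/1b- vitreous dominates",
      vignette(sp, findings = list(vitreous_cells_anterior = list(value = "present", grade = 3))),
      "spa_hla_b27", "criteria_not_met")
  add("spa/2a+ acute", vignette(sp, course = "acute"), "spa_hla_b27", "classified")
  add("spa/2a+ alternating", vignette(sp, laterality = "alternating_unilateral"),
      "spa_hla_b27", "classified")
  add("spa/2a- bilateral", vignette(sp, laterality = "bilateral"),
      "spa_hla_b27", "criteria_not_met")
  add("spa/2b+ chronic after recurrent",
      vignette(sp, course = "chronic_after_recurrent_acute"),
      "spa_hla_b27", "classified")
  add("spa/2b- plain chronic without dual positivity",
      vignette(sp, course = "chronic"), "spa_hla_b27", "criteria_not_met")
  add("spa/3+ ASAS only",
      vignette(sp, tests = list(hla_b27 = "negative", asas_spondyloarthritis = "positive")),
      "spa_hla_b27", "classified")
  add("spa/3- neither ASAS nor HLA-B27",
      vignette(sp, tests = list(hla_b27 = "negative")),
      "spa_hla_b27", "criteria_not_met")
  add("spa/4+ chronic with ASAS and HLA-B27",
      vignette(sp, course = "chronic",
               tests = list(asas_spondyloarthritis = "positive")),
      "spa_hla_b27", "classified")
  add("spa/4- chronic with HLA-B27 alone",
      vignette(sp, course = "chronic"), "spa_hla_b27", "criteria_not_met")
  add("spa/E1+ syphilis excludes",
      vignette(sp, tests = list(syphilis_serology_treponemal = "positive")),
      "spa_hla_b27", "excluded")
  add("spa/E1- treponemal negative", sp, "spa_hla_b27", "classified")
  add("spa/E2+ hilar adenopathy",
      vignette(sp, tests = list(chest_xray_bilateral_hilar_adenopathy = "positive")),
      "spa_hla_b27", "excluded")
  add("spa/E2+ granulomas",
      vignette(sp, tests = list(biopsy_noncaseating_granulomas = "positive")),
      "spa_hla_b27", "excluded")
  add("spa/E3+ aqueous CMV",
      vignette(sp, tests = list(pcr_aqueous_cmv = "positive")),
      "spa_hla_b27", "excluded")
  add("spa/E3+ aqueous VZV",
      vignette(sp, tests = list(pcr_aqueous_vzv = "positive")),
      "spa_hla_b27", "excluded")
  add("spa/E3- all aqueous PCRs negative", sp, "spa_hla_b27", "classified")

  ## --- Fuchs uveitis syndrome ----------------------------------------
  add("fuchs/1a+", fu, "fuchs_uveitis", "classified")
  add("fuchs/1a- no AC cells",
      vignette(fu, findings = list(anterior_chamber_cells = "absent")),
      "fuchs_uveitis", "criteria_not_met")
  add("fuchs/1b+ vitreous cells with AC inflammation",
      vignette(fu, findings = list(vitreous_cells_anterior = list(value = "present", grade = 1))),
      "fuchs_uveitis", "classified")
  add("fuchs/1c+ no retinitis", fu, "fuchs_uveitis", "classified")
  add("fuchs/1c- active retinitis",
      vignette(fu, findings = list(active_retinitis = "present")),
      "fuchs_uveitis", "criteria_not_met")
  add("fuchs/2+ unilateral", fu, "fuchs_uveitis", "classified")
  add("fuchs/2- bilateral", vignette(fu, laterality = "bilateral"),
      "fuchs_uveitis", "criteria_not_met")
  add("fuchs/3a+ heterochromia with rest of item 3 unknown",
      vignette(fu, findings = list(diffuse_iris_atrophy = NULL,
                                   stellate_keratic_precipitates = NULL)),
      "fuchs_uveitis", "classified")
  add("fuchs/3b+ atrophy and stellate KP",
      vignette(fu, findings = list(heterochromia = "absent",
                                   diffuse_iris_atrophy = "present",
                                   stellate_keratic_precipitates = "present")),
      "fuchs_uveitis", "classified")
  add("fuchs/3b- atrophy without stellate KP",
      vignette(fu, findings = list(heterochromia = "absent",
                                   diffuse_iris_atrophy = "present")),
      "fuchs_uveitis", "criteria_not_met")
  add("fuchs/4- endotheliitis",
      vignette(fu, findings = list(endotheliitis = "present")),
      "fuchs_uveitis", "criteria_not_met")
  add("fuchs/4- coin-shaped lesions",
      vignette(fu, findings = list(coin_shaped_endothelial_lesions = "present")),
      "fuchs_uveitis", "criteria_not_met")
  add("fuchs/E1+ syphilis excludes",
      vignette(fu, tests = list(syphilis_serology_treponemal = "positive")),
      "fuchs_uveitis", "excluded")
  add("fuchs/E2+ granulomas",
      vignette(fu, tests = list(biopsy_noncaseating_granulomas = "positive")),
      "fuchs_uveitis", "excluded")
  add("fuchs/E2- sarcoidosis workup negative", fu, "fuchs_uveitis", "classified")
  add("fuchs/E3+ aqueous HSV",
      vignette(fu, tests = list(pcr_aqueous_hsv = "positive")),
      "fuchs_uveitis", "excluded")

  ## --- Acute retinal necrosis ----------------------------------------
  add("arn/1+", ar, "arn", "classified")
  add("arn/1- no necrotizing retinitis",
      vignette(ar, findings = list(necrotizing_retinitis_peripheral = "absent")),
      "arn", "criteria_not_met")
  add("arn/2+ aqueous HSV with item 3 unknown", ar, "arn", "classified")
  add("arn/2+ vitreous VZV",
      vignette(ar, tests = list(pcr_aqueous_hsv = "negative",
                                pcr_vitreous_vzv = "positive")),
      "arn", "classified")
  add("arn/2- PCR negative, clinical picture unknown",
      vignette(ar, tests = list(pcr_aqueous_hsv = "negative",
                                pcr_aqueous_vzv = "negative",
                                pcr_vitreous_hsv = "negative",
                                pcr_vitreous_vzv = "negative")),
      "arn", "indeterminate")
  add("arn/3+ clinical picture without PCR",
      vignette(ar, tests = list(pcr_aqueous_hsv = "negative",
                                pcr_aqueous_vzv = "negative",
                                pcr_vitreous_hsv = "negative",
                                pcr_vitreous_vzv = "negative"),
               findings = list(confluent_retinitis = "present",
                               retinal_vascular_sheathing_or_occlusion = "present",
                               more_than_minimal_vitritis = "present")),
      "arn", "classified")
  add("arn/3- incomplete clinical picture",
      vignette(ar, tests = list(pcr_aqueous_hsv = "negative",
                                pcr_aqueous_vzv = "negative",
                                pcr_vitreous_hsv = "negative",
                                pcr_vitreous_vzv = "negative"),
               findings = list(confluent_retinitis = "present",
                               retinal_vascular_sheathing_or_occlusion = "present",
                               more_than_minimal_vitritis = "absent")),
      "arn", "criteria_not_met")
  add("arn/E1+ syphilis excludes",
      vignette(ar, tests = list(syphilis_serology_treponemal = "positive")),
      "arn", "excluded")
  add("arn/E2+ intraocular CMV in immunocompetent host",
      vignette(ar, tests = list(pcr_intraocular_cmv = "positive",
                                immunocompromised = "negative")),
      "arn", "excluded")
  add("arn/E2+ intraocular Toxoplasma",
      vignette(ar, tests = list(pcr_intraocular_toxoplasma = "positive",
                                immunocompromised = "negative")),
      "arn", "excluded")
  add("arn/E2+ escape clause incomplete (no second infection)",
      vignette(ar, tests = list(pcr_intraocular_cmv = "positive",
                                immunocompromised = "positive",
                                pcr_intraocular_hsv = "positive"),
               findings = list(morphologic_evidence_multiple_infections = "absent",
                               confluent_retinitis = "present",
                               retinal_vascular_sheathing_or_occlusion = "present",
                               more_than_minimal_vitritis = "present")),
      "arn", "excluded")
  add("arn/E2- full escape clause lifts the exclusion",
      vignette(ar, tests = list(pcr_intraocular_cmv = "positive",
                                immunocompromised = "positive",
                                pcr_intraocular_hsv = "positive"),
               findings = list(morphologic_evidence_multiple_infections = "present",
                               confluent_retinitis = "present",
                               retinal_vascular_sheathing_or_occlusion = "present",
                               more_than_minimal_vitritis = "present")),
      "arn", "classified")
  add("arn/E2- intraocular PCRs negative", ar, "arn", "classified")
  v
}
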