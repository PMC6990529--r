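# Shared domain constants (this file loads before the rest of R/).

# Mortality Risk Score
diagnosis_levels <- c("intrahepatic_cc", "perihilar_cc", "other")
risk_groups <- c("1", "2A", "2B", "3A", "3B", "4")
risk_group_descriptions <- c(
  "1" = "very low-risk", "2A" = "low-risk", "2B" = "low-risk",
  "3A" = "medium-risk", "3B" = "medium-risk", "4" = "high-risk"
)
risk_score_fields <- c(
  "age_years", "right_trisectionectomy", "inr", "ggt_u_per_l",
  "platelets_per_nl", "creatinine_mg_dl", "diagnosis", "asa_class"
)

# POSSUM
possum_phys_items <- c("age", "cardiac", "respiratory", "sbp", "pulse",
                       "gcs", "hb", "wcc", "urea", "sodium", "potassium",
                       "ecg")
possum_oper_items <- c("severity", "multiple", "blood_loss", "soiling",
                       "malignancy", "mode")
possum_grades <- c(1L, 2L, 4L, 8L)
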