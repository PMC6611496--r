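# in-code fixtures: nominal surgical cases and small cohorts

nominal_case <- function(eye_id = "E00001", patient_id = "P00001",
                         eye = "right", age_years = 57, k_d = 43.3,
                         acd_mm = 3.1, al_mm = 23.03, rx_pre_d = 1.85,
                         iol_implanted_d = 23.0, rx_post_d = 0.5,
                         udva_pre = 0.6, cdva_pre = 0.2, udva_post = 0.1,
                         cdva_post = 0.0, astig_pre_d = 1.0,
                         days_postop = 30, surgery_text = "",
                         finding_text = "", diagnosis_text = "") {
  data.frame(eye_id = eye_id, patient_id = patient_id, eye = eye,
             age_years = age_years, k_d = k_d, acd_mm = acd_mm,
             al_mm = al_mm, rx_pre_d = rx_pre_d,
             iol_implanted_d = iol_implanted_d, rx_post_d = rx_post_d,
             udva_pre = udva_pre, cdva_pre = cdva_pre,
             udva_post = udva_post, cdva_post = cdva_post,
             astig_pre_d = astig_pre_d, days_postop = days_postop,
             surgery_text = surgery_text, finding_text = finding_text,
             diagnosis_text = diagnosis_text, stringsAsFactors = FALSE)
}

nominal_cohort <- function(n = 10, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    nominal_case(
      eye_id = sprintf("E%05d", i), patient_id = sprintf("P%05d", i),
      age_years = round(runif(1, 40, 75)), k_d = runif(1, 41, 45.5),
      acd_mm = runif(1, 2.6, 3.6), al_mm = runif(1, 21.5, 25),
      rx_pre_d = runif(1, -2, 4), iol_implanted_d = sample(seq(18, 26, 0.5), 1),
      rx_post_d = sample(seq(-1, 1, 0.125), 1)
    )
  }))
}

# random in-range eyes for property checks
random_eyes <- function(n, seed) {
  set.seed(seed)
  data.frame(
    k_d = runif(n, 39.5, 47.5),
    al_mm = runif(n, 20, 26.2),
    iol_d = runif(n, 10, 32),
    rx_post_d = runif(n, -2, 2)
  )
}
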