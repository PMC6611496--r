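test_that("record filters exclude with the documented first-match reasons", {
  coh <- rbind(
    nominal_case(eye_id = "E1"),
    nominal_case(eye_id = "E2", al_mm = 14.0),
    nominal_case(eye_id = "E3", cdva_post = 0.35, udva_post = 0.5),
    nominal_case(eye_id = "E4", acd_mm = 0.5),
    nominal_case(eye_id = "E5", astig_pre_d = 3.2),
    nominal_case(eye_id = "E6", rx_post_d = NA),
    nominal_case(eye_id = "E7", days_postop = 10),
    nominal_case(eye_id = "E8", udva_post = 0.0, cdva_post = 0.1),
    nominal_case(eye_id = "E9", age_years = 101)
  )
  out <- apply_record_filters(coh)
  r <- out$exclusion_reason
  expect_true(is.na(r[1]))
  expect_equal(r[2], "AL range")
  expect_equal(r[3], "postop CDVA")
  expect_equal(r[4], "ACD range")
  expect_equal(r[5], "astigmatism")
  expect_equal(r[6], "incomplete")
  expect_equal(r[7], "days postop")
  expect_equal(r[8], "acuity order")
  expect_equal(r[9], "age range")
})

test_that("equal UDVA and CDVA is retained by default, excluded in strict mode", {
  coh <- nominal_case(udva_post = 0.1, cdva_post = 0.1)
  expect_true(is.na(apply_record_filters(coh)$exclusion_reason))
  strict <- filter_criteria(udva_cdva_strict = TRUE)
  expect_equal(apply_record_filters(coh, strict)$exclusion_reason,
               "acuity order")
})

test_that("filtering is idempotent and conserves cases", {
  coh <- rbind(nominal_cohort(20, seed = 2),
               nominal_case(eye_id = "EBAD", al_mm = 14))
  once <- apply_record_filters(coh)
  twice <- apply_record_filters(once)
  expect_identical(once, twice)
  expect_equal(sum(is.na(once$exclusion_reason)) +
                 sum(!is.na(once$exclusion_reason)), nrow(coh))
})

test_that("keyword exclusion matches case-insensitive substrings per field", {
  r <- keyword_exclusion(diagnosis_text = "s/p LASIK 2009")
  expect_true(r$excluded)
  expect_equal(r$matched_term, "LASIK")
  r2 <- keyword_exclusion(finding_text = "guttata centralis")
  expect_true(r2$excluded)
  expect_equal(r2$matched_term, "guttat")
  expect_false(keyword_exclusion("", "", "")$excluded)
  # surgery list does not apply to diagnosis text
  expect_false(keyword_exclusion(diagnosis_text = "ruptura")$excluded)
  r3 <- keyword_exclusion(surgery_text = "RUPTURA pouzdra")
  expect_true(r3$excluded)
})

test_that("fellow-eye filter excludes discordant pairs, keeps concordant and single eyes", {
  coh <- rbind(
    nominal_case(eye_id = "E1", patient_id = "PA", eye = "right", al_mm = 23.0),
    nominal_case(eye_id = "E2", patient_id = "PA", eye = "left", al_mm = 24.5),
    nominal_case(eye_id = "E3", patient_id = "PB", eye = "right", al_mm = 23.0),
    nominal_case(eye_id = "E4", patient_id = "PB", eye = "left", al_mm = 23.8),
    nominal_case(eye_id = "E5", patient_id = "PC", eye = "right", al_mm = 26.0)
  )
  out <- fellow_eye_al_filter(apply_record_filters(coh))
  expect_equal(out$exclusion_reason[1:2], rep("fellow-eye AL", 2))
  expect_true(all(is.na(out$exclusion_reason[3:5])))

  bad <- rbind(coh[1:2, ], nominal_case(eye_id = "E6", patient_id = "PA"))
  expect_error(fellow_eye_al_filter(apply_record_filters(bad)),
               "more than two eyes")
})

test_that("three-sigma filter matches the direct mean/STD oracle", {
  coh <- nominal_cohort(11, seed = 4)
  coh$rx_pre_d <- c(1:10, 1000)
  coh$exclusion_reason <- NA_character_
  out <- sigma_filter(coh)
  m <- mean(coh$rx_pre_d); s <- sd(coh$rx_pre_d)
  expect_equal(which(!is.na(out$exclusion_reason)),
               which(abs(coh$rx_pre_d - m) > 3 * s))
  expect_equal(out$exclusion_reason[11], "sigma:rx_pre_d")

  # identical values: zero variance skipped with warning, nothing excluded
  coh2 <- nominal_cohort(5, seed = 5)
  coh2$age_years <- 60
  coh2$exclusion_reason <- NA_character_
  expect_warning(out2 <- sigma_filter(coh2, variables = "age_years"),
                 "zero variance")
  expect_true(all(is.na(out2$exclusion_reason)))
})

test_that("a case at the three-sigma boundary is retained (strict inequality)", {
  coh <- nominal_cohort(12, seed = 6)
  x <- c(-1, -1, -1, -1, -1, 0, 1, 1, 1, 1, 1)
  # closed form for v with v = mean + 3*sd over the 12 values:
  # mean = v/12, var = (10 + 11 v^2/12)/11  =>  v = 12*sqrt(90/143)
  v <- 12 * sqrt(90 / 143) * (1 - 1e-12)   # a hair inside the boundary
  coh$rx_pre_d <- c(x, v)
  coh$exclusion_reason <- NA_character_
  out <- sigma_filter(coh, variables = "rx_pre_d")
  expect_true(all(is.na(out$exclusion_reason)))
  # a case clearly beyond the boundary is excluded
  coh$rx_pre_d[12] <- v * 1.2
  out2 <- sigma_filter(coh, variables = "rx_pre_d")
  expect_equal(out2$exclusion_reason[12], "sigma:rx_pre_d")
})

test_that("selection/verification split honors the fraction and the seed", {
  coh <- nominal_cohort(50, seed = 7)
  big <- coh[rep(1:50, length.out = 2194), ]
  big$eye_id <- sprintf("E%05d", 1:2194)
  sp <- split_cohort(big, 0.7, seed = 123)
  expect_true(nrow(sp$selection) %in% c(1535, 1536))
  expect_equal(nrow(sp$selection) + nrow(sp$verification), 2194)

  sp2 <- split_cohort(big, 0.7, seed = 123)
  expect_identical(sp$selection$eye_id, sp2$selection$eye_id)
  sp3 <- split_cohort(big, 0.7, seed = 124)
  expect_false(identical(sp$selection$eye_id, sp3$selection$eye_id))

  expect_error(split_cohort(big, 1.0, seed = 1), "selection_fraction")
  expect_error(split_cohort(big[0, ], 0.7, seed = 1), "empty")
})

test_that("min-max normalizer maps to [-1, 1] and round-trips", {
  tab <- data.frame(a = c(0, 2.5, 10), b = c(-5, 0, 5))
  nz <- fit_normalizer(tab)
  expect_equal(normalize(5, nz, "a"), 0)
  expect_equal(normalize(0, nz, "a"), -1)
  expect_equal(normalize(10, nz, "a"), 1)
  x <- seq(-5, 5, 0.1)
  expect_equal(denormalize(normalize(x, nz, "b"), nz, "b"), x,
               tolerance = 1e-12)
  expect_error(fit_normalizer(data.frame(c = rep(1, 3))), "constant")
})

test_that("out-of-range clearing drops strict outliers, keeps boundaries", {
  sel <- data.frame(al_mm = c(21, 23, 25), k_d = c(40, 43, 46))
  nz <- fit_normalizer(sel)
  ver <- data.frame(al_mm = c(22, 25, 25.5, 21), k_d = c(41, 46, 42, 39))
  out <- clear_out_of_range(ver, nz)
  expect_equal(nrow(out$table), 2)       # rows 1 and 2 (boundaries kept)
  expect_equal(out$removed$removal_reason,
               c("out-of-range:al_mm", "out-of-range:k_d"))
  # verification inside selection ranges: nothing removed
  out2 <- clear_out_of_range(data.frame(al_mm = 23, k_d = 44), nz)
  expect_equal(nrow(out2$removed), 0)
})

test_that("training-table targets follow the vergence-model oracle", {
  coh <- rbind(
    nominal_case(eye_id = "E1", rx_post_d = 0, iol_implanted_d = 22.5),
    nominal_case(eye_id = "E2", k_d = 43.3, al_mm = 23.03,
                 iol_implanted_d = 23.0, rx_post_d = 0.5)
  )
  tab <- build_training_table(coh)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$iol_ideal_d[1], 22.5)          # zero residual -> implanted
  expect_equal(tab$iol_ideal_d[2], 23.72, tolerance = 0.01)
  # normalized output lies in [-1, 1]
  coh10 <- nominal_cohort(10, seed = 8)
  tab10 <- build_training_table(coh10)
  nz <- fit_normalizer(tab10, c("k_d", "acd_mm", "al_mm", "age_years",
                                "rx_pre_d", "iol_ideal_d"))
  tabn <- build_training_table(coh10, normalizer = nz)
  expect_true(all(tabn$iol_ideal_d >= -1 & tabn$iol_ideal_d <= 1))
})

test_that("self-consistent noise-free cohort recovers the true required power", {
  cfg <- synthetic_config(n_eyes = 200, seed = 31, sigma_elp_mm = 0,
                          sigma_meas_d = 0, rx_quantum_d = 0)
  cfg$a_constant_surgeon <- cfg$a_constant_true
  cfg$consts$iol_step_d <- 1e-9    # effectively no rounding
  g <- generate_cohort(cfg)
  consts <- optics_constants(a_constant = cfg$a_constant_true)
  tab <- build_training_table(g$cohort, consts)
  expect_lt(max(abs(tab$iol_ideal_d - g$ground_truth$iol_required_d)), 1e-6)
})

test_that("prepare_cohort is deterministic and internally consistent", {
  cfg <- synthetic_config(n_eyes = 300, seed = 13,
                          contamination_fraction = 0.05)
  g <- generate_cohort(cfg)
  p1 <- prepare_cohort(g$cohort, seed = 99)
  p2 <- prepare_cohort(g$cohort, seed = 99)
  expect_identical(p1$selection$eye_id, p2$selection$eye_id)
  expect_identical(p1$verification_norm, p2$verification_norm)
  # conservation across retained/excluded
  expect_equal(nrow(p1$cohort), nrow(g$cohort))
  # all normalized values in range
  nv <- as.matrix(p1$selection_norm[, c("k_d", "acd_mm", "al_mm",
                                        "age_years", "rx_pre_d")])
  expect_true(all(nv >= -1 & nv <= 1))
  vv <- as.matrix(p1$verification_norm[, c("k_d", "acd_mm", "al_mm",
                                           "age_years", "rx_pre_d")])
  expect_true(all(vv >= -1 & vv <= 1))
})
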