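#' Configuration of the synthetic surgical cohort generator
#'
#' Marginal distributions default to the study population: truncated
#' normals for age, keratometry, anterior chamber depth and axial length
#' (mean/SD/min/max as observed in the selection set), and a right-skewed
#' two-component normal mixture for the preoperative refraction. Axial
#' length and preoperative refraction are negatively coupled through a
#' Gaussian copula (long eyes are myopic). Outcomes come from the forward
#' vergence model: the "surgeon" selects the lens with the SRK/T formula at
#' `a_constant_surgeon`, while the eye's true effective lens position is
#' drawn around the SRK/T prediction at `a_constant_true`; the gap between
#' the two constants induces the systematic myopic bias of the clinical
#' baseline. Postoperative refraction carries Gaussian measurement noise
#' and phoropter quantization.
#'
#' @param n_eyes number of eyes to generate.
#' @param seed master seed; all draws derive from it.
#' @param marginals named list of `c(mean, sd, min, max)` for `age_years`,
#'   `k_d`, `acd_mm`, `al_mm`, and `c(mean1, sd1, mean2, sd2, w2, min,
#'   max)` for `rx_pre_d` (mixture: weight `w2` on the second, more
#'   hyperopic component).
#' @param rho_al_rxpre Gaussian-copula correlation between AL and Rx_pre.
#' @param fellow_eye_corr within-patient copula correlation for K/ACD/AL.
#' @param sigma_elp_mm SD of the per-eye true-ELP deviation from the SRK/T
#'   prediction (mm).
#' @param sigma_meas_d SD of refraction measurement noise (D).
#' @param rx_quantum_d refraction quantization step (D; 0 disables).
#' @param a_constant_true A-constant generating the true lens position.
#' @param a_constant_surgeon A-constant the simulated surgeon plans with.
#' @param fellow_eye_fraction share of patients contributing both eyes.
#' @param contamination_fraction share of cases given a random
#'   filter-violating defect (for exclusion-pipeline testing).
#' @param consts base [optics_constants()] (step/range used for lens
#'   selection).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_eyes = 2194, seed = 1L,
                             marginals = list(
                               age_years = c(mean = 56.89, sd = 7.25,
                                             min = 36, max = 78),
                               k_d = c(mean = 43.27, sd = 1.40,
                                       min = 39.39, max = 47.51),
                               acd_mm = c(mean = 3.10, sd = 0.32,
                                          min = 2.21, max = 4.10),
                               al_mm = c(mean = 23.03, sd = 0.92,
                                         min = 19.94, max = 26.26),
                               rx_pre_d = c(mean1 = 1.60, sd1 = 1.20,
                                            mean2 = 3.30, sd2 = 2.00,
                                            w2 = 0.15, min = -3.88,
                                            max = 6.63)
                             ),
                             rho_al_rxpre = -0.50,
                             fellow_eye_corr = 0.90,
                             sigma_elp_mm = 0.25,
                             sigma_meas_d = 0.15,
                             rx_quantum_d = 0.125,
                             a_constant_true = 118.62,
                             a_constant_surgeon = 119.1,
                             fellow_eye_fraction = 0.32,
                             contamination_fraction = 0,
                             consts = optics_constants()) {
  stopifnot(n_eyes >= 1, sigma_elp_mm >= 0, sigma_meas_d >= 0,
            rx_quantum_d >= 0,
            fellow_eye_fraction >= 0, fellow_eye_fraction <= 1,
            contamination_fraction >= 0, contamination_fraction <= 1,
            abs(rho_al_rxpre) < 1)
  structure(
    list(n_eyes = as.integer(n_eyes), seed = as.integer(seed),
         marginals = marginals, rho_al_rxpre = rho_al_rxpre,
         fellow_eye_corr = fellow_eye_corr,
         sigma_elp_mm = sigma_elp_mm, sigma_meas_d = sigma_meas_d,
         rx_quantum_d = rx_quantum_d,
         a_constant_true = a_constant_true,
         a_constant_surgeon = a_constant_surgeon,
         fellow_eye_fraction = fellow_eye_fraction,
         contamination_fraction = contamination_fraction,
         consts = consts),
    class = "synthetic_config"
  )
}

# truncated-normal quantile transform of a uniform draw
qtruncnorm_u <- function(u, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, length(u)))
  pa <- stats::pnorm((lo - mean) / sd)
  pb <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(pa + u * (pb - pa))
}

# quantile of the truncated two-component normal mixture, by numeric
# inversion of its CDF on a fine grid
qmixture_u <- function(u, pars) {
  cdf <- function(x) {
    (1 - pars["w2"]) * stats::pnorm(x, pars["mean1"], pars["sd1"]) +
      pars["w2"] * stats::pnorm(x, pars["mean2"], pars["sd2"])
  }
  lo <- pars["min"]; hi <- pars["max"]
  grid <- seq(lo, hi, length.out = 4096)
  cg <- cdf(grid)
  # renormalize to the truncation interval
  cg <- (cg - cg[1]) / (cg[length(cg)] - cg[1])
  stats::approx(cg, grid, xout = u, ties = "ordered", rule = 2)$y
}

#' Sample biometry for a structured cohort of patients and eyes
#'
#' Draws patient/eye structure (a configurable share of patients
#' contributes both eyes), then per-eye biometry through a Gaussian copula:
#' fellow eyes share a patient-level latent factor for K, ACD and AL (age
#' is identical within patient), and the AL and Rx_pre latents are
#' negatively correlated. Marginals are exact truncated normals (mixture
#' for Rx_pre) by quantile transform.
#'
#' @param config a [synthetic_config()].
#' @param n number of eyes (defaults to `config$n_eyes`).
#' @param seed seed (defaults to `config$seed`).
#' @return data.frame with `eye_id`, `patient_id`, `eye` and the five
#'   biometry predictors.
#' @export
sample_biometry <- function(config = synthetic_config(),
                            n = config$n_eyes, seed = config$seed) {
  set.seed(derive_seed(seed, "biometry"))
  m <- config$marginals

  # patient structure: two-eye patients contribute 2 eyes each
  p2 <- config$fellow_eye_fraction
  n_pat_est <- ceiling(n / (1 + p2))
  both <- stats::runif(n_pat_est + n) < p2   # oversample, trim to n eyes
  eyes_per <- ifelse(both, 2L, 1L)
  cum <- cumsum(eyes_per)
  n_pat <- which(cum >= n)[1]
  eyes_per <- eyes_per[seq_len(n_pat)]
  if (cum[n_pat] > n) eyes_per[n_pat] <- eyes_per[n_pat] - (cum[n_pat] - n)

  patient_id <- rep(sprintf("P%05d", seq_len(n_pat)), eyes_per)
  eye <- unlist(lapply(eyes_per, function(k) c("right", "left")[seq_len(k)]),
                use.names = FALSE)
  pat_idx <- rep(seq_len(n_pat), eyes_per)

  rho_p <- config$fellow_eye_corr
  eye_latent <- function() {
    zp <- stats::rnorm(n_pat)[pat_idx]
    ze <- stats::rnorm(n)
    sqrt(rho_p) * zp + sqrt(1 - rho_p) * ze
  }

  z_age <- stats::rnorm(n_pat)[pat_idx]        # identical within patient
  z_k <- eye_latent()
  z_acd <- eye_latent()
  z_al <- eye_latent()
  rho <- config$rho_al_rxpre
  z_rx <- rho * z_al + sqrt(1 - rho^2) * stats::rnorm(n)

  data.frame(
    eye_id = sprintf("E%05d", seq_len(n)),
    patient_id = patient_id, eye = eye,
    age_years = round(qtruncnorm_u(stats::pnorm(z_age),
                                   m$age_years["mean"], m$age_years["sd"],
                                   m$age_years["min"], m$age_years["max"])),
    k_d = qtruncnorm_u(stats::pnorm(z_k), m$k_d["mean"], m$k_d["sd"],
                       m$k_d["min"], m$k_d["max"]),
    acd_mm = qtruncnorm_u(stats::pnorm(z_acd), m$acd_mm["mean"],
                          m$acd_mm["sd"], m$acd_mm["min"], m$acd_mm["max"]),
    al_mm = qtruncnorm_u(stats::pnorm(z_al), m$al_mm["mean"], m$al_mm["sd"],
                         m$al_mm["min"], m$al_mm["max"]),
    rx_pre_d = qmixture_u(stats::pnorm(z_rx), m$rx_pre_d),
    stringsAsFactors = FALSE
  )
}

#' Simulate the clinic's lens selection
#'
#' The surgeon targets emmetropia at the SRK/T-predicted lens position for
#' the planning A-constant — the emmetropic power is the exact inversion
#' of the same vergence model that generates the outcome, so with matching
#' constants and no noise or rounding the simulated surgery is
#' self-consistent (zero residual by construction). The power is rounded
#' to the available lens step (ties toward the lower power) and clamped to
#' the available range.
#'
#' @param biometry data.frame from [sample_biometry()].
#' @param config a [synthetic_config()].
#' @return implanted IOL power (D) per eye.
#' @export
simulate_surgery <- function(biometry, config = synthetic_config()) {
  consts <- config$consts
  consts$a_constant <- config$a_constant_surgeon
  elp <- srkt_elp(biometry$k_d, biometry$al_mm, consts)$elp_mm
  p <- iol_required_for_emmetropia(biometry$k_d, biometry$al_mm, elp, consts)
  round_to_step(p, consts)
}

quantize <- function(x, step) {
  if (step <= 0) return(x)
  round(x / step) * step
}

#' Simulate the surgical outcome through the forward vergence model
#'
#' The eye's true effective lens position is the SRK/T prediction at the
#' true A-constant plus a Gaussian per-eye deviation; the noise-free
#' outcome is the vergence-model refraction of the implanted lens at that
#' position; the recorded refraction adds measurement noise and phoropter
#' quantization. Ancillary clinical fields are filled with filter-passing
#' defaults; a configurable fraction of cases receives one random
#' filter-violating defect for exclusion-pipeline testing.
#'
#' @param biometry data.frame from [sample_biometry()].
#' @param iol_implanted implanted powers (D) from [simulate_surgery()].
#' @param config a [synthetic_config()].
#' @param seed seed (defaults to `config$seed`).
#' @return list with `cohort` (full surgical-case data.frame) and
#'   `ground_truth` (`eye_id`, `true_elp_mm`, `iol_required_d`,
#'   `rx_post_clean_d`).
#' @export
simulate_outcome <- function(biometry, iol_implanted,
                             config = synthetic_config(),
                             seed = config$seed) {
  set.seed(derive_seed(seed, "outcome"))
  n <- nrow(biometry)
  consts_true <- config$consts
  consts_true$a_constant <- config$a_constant_true

  elp_pred <- srkt_elp(biometry$k_d, biometry$al_mm, consts_true)$elp_mm
  true_elp <- elp_pred + stats::rnorm(n, 0, config$sigma_elp_mm)
  iol_required <- iol_required_for_emmetropia(biometry$k_d, biometry$al_mm,
                                              true_elp, consts_true)
  rx_clean <- rx_theor_post(biometry$k_d, biometry$al_mm, true_elp,
                            iol_implanted, consts_true)
  rx_post <- quantize(rx_clean + stats::rnorm(n, 0, config$sigma_meas_d),
                      config$rx_quantum_d)

  cohort <- data.frame(
    biometry,
    iol_implanted_d = iol_implanted,
    rx_post_d = rx_post,
    udva_pre = 0.60, cdva_pre = 0.20,
    udva_post = pmax(0.02, round(abs(rx_post) * 0.25, 2)), cdva_post = 0.0,
    astig_pre_d = pmin(abs(stats::rnorm(n, 0.8, 0.5)), 2.9),
    days_postop = 30L,
    surgery_text = "", finding_text = "", diagnosis_text = "",
    stringsAsFactors = FALSE
  )

  if (config$contamination_fraction > 0) {
    n_bad <- round(config$contamination_fraction * n)
    bad <- sample.int(n, n_bad)
    defect <- sample(5, n_bad, replace = TRUE)
    cohort$cdva_post[bad[defect == 1]] <- 0.5
    cohort$astig_pre_d[bad[defect == 2]] <- 3.5
    cohort$days_postop[bad[defect == 3]] <- 10L
    cohort$diagnosis_text[bad[defect == 4]] <- "st. p. LASIK"
    cohort$rx_post_d[bad[defect == 5]] <- NA_real_
  }

  list(
    cohort = cohort,
    ground_truth = data.frame(
      eye_id = biometry$eye_id,
      true_elp_mm = true_elp,
      iol_required_d = iol_required,
      rx_post_clean_d = rx_clean,
      stringsAsFactors = FALSE
    )
  )
}

#' Generate a complete synthetic surgical cohort
#'
#' Composition of [sample_biometry()], [simulate_surgery()] and
#' [simulate_outcome()]: a ready-to-filter cohort plus the latent ground
#' truth (true lens position, required power, noise-free outcome), which
#' the models never see.
#'
#' @param config a [synthetic_config()].
#' @return list with `cohort` and `ground_truth` data.frames.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  bio <- sample_biometry(config)
  iol <- simulate_surgery(bio, config)
  simulate_outcome(bio, iol, config)
}
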