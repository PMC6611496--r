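#' Optical constants for the pseudophakic vergence model
#'
#' Bundles the constants used by the SRK/T effective-lens-position (ELP)
#' chain and by the reversed vergence formula. Defaults follow the usual
#' clinical conventions: a 12 mm spectacle vertex distance, a reduced
#' intraocular index of 1.336 (stored x1000), the 337.5/K keratometric
#' radius convention, and an A-constant of 119.1 for the implanted lens
#' model.
#'
#' @param vertex_distance_mm spectacle-to-cornea distance in mm (>= 0).
#' @param n_aqueous reduced refractive index of the intraocular media,
#'   times 1000 (default 1336).
#' @param keratometric_index_numerator numerator of the corneal-radius
#'   conversion, so that r = numerator / K in mm (default 337.5).
#' @param n_cornea_minus_1 fictitious corneal index minus one, used by the
#'   SRK/T power formula (default 0.333).
#' @param a_constant lens A-constant on the diopter scale.
#' @param iol_step_d commercially available IOL power increment in D.
#' @param iol_min_d,iol_max_d available IOL power range in D.
#' @return an object of class `optics_constants`.
#' @examples
#' oc <- optics_constants(a_constant = 119.1)
#' srkt_elp(43.3, 23.03, oc)$elp_mm
#' @export
optics_constants <- function(vertex_distance_mm = 12,
                             n_aqueous = 1336,
                             keratometric_index_numerator = 337.5,
                             n_cornea_minus_1 = 0.333,
                             a_constant = 119.1,
                             iol_step_d = 0.5,
                             iol_min_d = 6,
                             iol_max_d = 35) {
  stopifnot(
    is.finite(vertex_distance_mm), vertex_distance_mm >= 0,
    is.finite(n_aqueous), n_aqueous > 1000,
    is.finite(keratometric_index_numerator), keratometric_index_numerator > 0,
    is.finite(a_constant), a_constant > 0,
    is.finite(iol_step_d), iol_step_d > 0,
    iol_min_d < iol_max_d
  )
  structure(
    list(
      vertex_distance_mm = vertex_distance_mm,
      n_aqueous = n_aqueous,
      keratometric_index_numerator = keratometric_index_numerator,
      n_cornea_minus_1 = n_cornea_minus_1,
      a_constant = a_constant,
      iol_step_d = iol_step_d,
      iol_min_d = iol_min_d,
      iol_max_d = iol_max_d
    ),
    class = "optics_constants"
  )
}

check_biometry_domain <- function(k_d, al_mm) {
  if (any(!is.finite(k_d)) || any(k_d < 30) || any(k_d > 60)) {
    stop("k_d out of physiological domain [30, 60] D", call. = FALSE)
  }
  if (any(!is.finite(al_mm)) || any(al_mm < 15) || any(al_mm > 40)) {
    stop("al_mm out of physiological domain [15, 40] mm", call. = FALSE)
  }
  invisible(TRUE)
}

#' SRK/T effective lens position and intermediates
#'
#' Evaluates the SRK/T chain: corneal radius from mean keratometry, the
#' corrected axial length (quadratic shortening beyond 24.2 mm), computed
#' corneal width, corneal height (with the square-root argument clamped at
#' zero for the steep-cornea degeneracy), the A-constant-derived ACD
#' constant, and finally ELP = corneal height + offset. All arguments are
#' vectorised.
#'
#' @param k_d mean keratometry in D (30-60).
#' @param al_mm axial length in mm (15-40).
#' @param consts an [optics_constants()] object.
#' @return a data.frame of class `srkt_intermediates` with columns
#'   `r_mm`, `lcor_mm`, `cw_mm`, `h_mm`, `acd_const_mm`, `offset_mm`,
#'   `elp_mm`, `rethick_mm`, `lopt_mm`.
#' @export
srkt_elp <- function(k_d, al_mm, consts = optics_constants()) {
  check_biometry_domain(k_d, al_mm)
  n <- max(length(k_d), length(al_mm))
  k_d <- rep_len(k_d, n); al_mm <- rep_len(al_mm, n)

  r <- consts$keratometric_index_numerator / k_d
  lcor <- ifelse(al_mm <= 24.2, al_mm, -3.446 + 1.716 * al_mm - 0.0237 * al_mm^2)
  cw <- -5.41 + 0.58412 * lcor + 0.098 * k_d
  h <- r - sqrt(pmax(r^2 - cw^2 / 4, 0))
  acd_const <- 0.62467 * consts$a_constant - 68.747
  offset <- acd_const - 3.336
  elp <- h + offset
  rethick <- 0.65696 - 0.02029 * al_mm
  lopt <- al_mm + rethick

  structure(
    data.frame(
      r_mm = r, lcor_mm = lcor, cw_mm = cw, h_mm = h,
      acd_const_mm = acd_const, offset_mm = offset, elp_mm = elp,
      rethick_mm = rethick, lopt_mm = lopt
    ),
    class = c("srkt_intermediates", "data.frame")
  )
}

#' SRK/T emmetropic IOL power
#'
#' The theoretical (unrounded) lens power that targets emmetropia for the
#' given biometry, from the SRK/T thin-lens power formula using the optical
#' axial length (axial length + retinal thickness correction) and the
#' SRK/T ELP.
#'
#' @inheritParams srkt_elp
#' @return emmetropic IOL power in D (vector).
#' @export
srkt_power_emmetropia <- function(k_d, al_mm, consts = optics_constants()) {
  s <- srkt_elp(k_d, al_mm, consts)
  na <- consts$n_aqueous / 1000
  ncm1 <- consts$n_cornea_minus_1
  r <- s$r_mm; lopt <- s$lopt_mm; elp <- s$elp_mm
  if (any(lopt <= elp)) {
    stop("degenerate geometry: optical axial length not beyond ELP", call. = FALSE)
  }
  1000 * na * (na * r - ncm1 * lopt) /
    ((lopt - elp) * (na * r - ncm1 * elp))
}

#' Simulated clinical IOL selection
#'
#' Rounds the SRK/T emmetropic power to the nearest commercially available
#' step and clamps to the available range. Ties at a half-step round toward
#' the lower (myopic-safe) power.
#'
#' @inheritParams srkt_elp
#' @return implanted IOL power in D (vector).
#' @export
clinical_iol_choice <- function(k_d, al_mm, consts = optics_constants()) {
  round_to_step(srkt_power_emmetropia(k_d, al_mm, consts), consts)
}

# nearest available lens power; ties round toward the lower (myopic-safe)
# power; clamped to the available range
round_to_step <- function(p, consts) {
  step <- consts$iol_step_d
  rounded <- ceiling(p / step - 0.5) * step
  pmin(pmax(rounded, consts$iol_min_d), consts$iol_max_d)
}

#' Theoretical postoperative refraction (reversed vergence formula)
#'
#' Back-propagates the vergence required to focus on the retina through the
#' implanted lens and the cornea to the spectacle plane. The chain, with K,
#' IOL and the intermediate vergences V1, V3 in diopters and AL, ELP, V in
#' mm, is
#' \deqn{V_3 = 1336/(AL - ELP)}
#' \deqn{1/V_1 = ELP/1336 + 1/(V_3 - IOL)}
#' \deqn{Rx = 1 / ( V/1000 - 1/(K - V_1) )}
#' Positive values are hyperopic residuals. With a zero vertex distance the
#' chain reduces to Rx = V1 - K (the corneal-plane residual).
#'
#' @inheritParams srkt_elp
#' @param elp_mm effective lens position in mm (cornea to lens plane).
#' @param iol_d implanted IOL power in D.
#' @return spectacle-plane refraction in D (vector).
#' @export
rx_theor_post <- function(k_d, al_mm, elp_mm, iol_d, consts = optics_constants()) {
  n <- max(length(k_d), length(al_mm), length(elp_mm), length(iol_d))
  k_d <- rep_len(k_d, n); al_mm <- rep_len(al_mm, n)
  elp_mm <- rep_len(elp_mm, n); iol_d <- rep_len(iol_d, n)
  if (any(!is.finite(c(k_d, al_mm, elp_mm, iol_d)))) {
    stop("non-finite input to rx_theor_post", call. = FALSE)
  }
  if (any(al_mm <= elp_mm)) {
    stop("axial length must exceed ELP", call. = FALSE)
  }
  na1000 <- consts$n_aqueous
  v3 <- na1000 / (al_mm - elp_mm)
  if (any(abs(v3 - iol_d) < 1e-12)) {
    stop("singular vergence: IOL power equals required vergence at lens plane",
         call. = FALSE)
  }
  v1 <- 1 / (elp_mm / na1000 + 1 / (v3 - iol_d))
  # corneal-plane transfer written as e/(d*e - 1) with e = K - V1, d = V/1000:
  # algebraically equal to 1/(d - 1/e) but continuous through the zero-residual
  # point e = 0; genuinely singular only when the eye's far point falls on the
  # spectacle plane (d*e = 1)
  e <- k_d - v1
  d <- consts$vertex_distance_mm / 1000
  if (any(abs(d * e - 1) < 1e-12)) {
    stop("singular vergence: far point at the spectacle plane", call. = FALSE)
  }
  e / (d * e - 1)
}

#' Refraction change per 0.5 D of IOL power
#'
#' The spectacle-plane dioptric change produced by increasing the implanted
#' power by half a diopter; positive for physiological eyes (more plus power
#' pushes the eye myopic).
#'
#' @inheritParams rx_theor_post
#' @return Rx(IOL) - Rx(IOL + 0.5) in D.
#' @export
rx_05iol <- function(k_d, al_mm, elp_mm, iol_d, consts = optics_constants()) {
  rx_theor_post(k_d, al_mm, elp_mm, iol_d, consts) -
    rx_theor_post(k_d, al_mm, elp_mm, iol_d + 0.5, consts)
}

#' Ideal IOL power for an operated eye
#'
#' The power that would have zeroed the postoperative refraction, from the
#' implanted power, the achieved refraction and the eye-specific refraction
#' change per 0.5 D of IOL power:
#' IOL_ideal = IOL_implanted + (Rx_post / Rx_05IOL) * 0.5.
#'
#' @param iol_implanted_d implanted power in D.
#' @param rx_post_d achieved postoperative spherical-equivalent refraction in D.
#' @param rx_05iol_d refraction change per 0.5 D of IOL power (must be > 0).
#' @return ideal IOL power in D.
#' @export
iol_ideal <- function(iol_implanted_d, rx_post_d, rx_05iol_d) {
  if (any(!is.finite(rx_05iol_d)) || any(rx_05iol_d <= 0)) {
    stop("rx_05iol_d must be positive", call. = FALSE)
  }
  iol_implanted_d + (rx_post_d / rx_05iol_d) * 0.5
}

#' Back-calculated refraction for a predicted IOL power
#'
#' The residual refraction the eye would have shown had the predicted power
#' been implanted instead of the actual one:
#' Rx_predicted = ((IOL_implanted - IOL_predicted) / 0.5) * Rx_05IOL + Rx_post.
#' Substituting the ideal power cancels algebraically to zero.
#'
#' @inheritParams iol_ideal
#' @param iol_predicted_d model-predicted power in D.
#' @return predicted residual refraction in D.
#' @export
rx_predicted <- function(iol_implanted_d, iol_predicted_d, rx_05iol_d, rx_post_d) {
  if (any(!is.finite(rx_05iol_d)) || any(rx_05iol_d <= 0)) {
    stop("rx_05iol_d must be positive", call. = FALSE)
  }
  ((iol_implanted_d - iol_predicted_d) / 0.5) * rx_05iol_d + rx_post_d
}

#' Required IOL power for a target of emmetropia at a known lens position
#'
#' Inverts the vergence chain in closed form: the power P satisfying
#' Rx = 0 at the given ELP, i.e. V1 = K, so
#' P = V3 - 1/(1/K - ELP/1336). Used by the synthetic generator to define
#' ground-truth required power; the vertex distance drops out at zero
#' residual.
#'
#' @inheritParams rx_theor_post
#' @return IOL power in D that zeroes the spectacle refraction.
#' @export
iol_required_for_emmetropia <- function(k_d, al_mm, elp_mm,
                                        consts = optics_constants()) {
  if (any(al_mm <= elp_mm)) stop("axial length must exceed ELP", call. = FALSE)
  na1000 <- consts$n_aqueous
  v3 <- na1000 / (al_mm - elp_mm)
  v3 - 1 / (1 / k_d - elp_mm / na1000)
}
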