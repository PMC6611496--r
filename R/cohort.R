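#' Default inclusion/exclusion criteria for cohort cleaning
#'
#' Range bounds and keyword lists used by [apply_record_filters()]. The
#' defaults encode the clinical screening rules of the study population:
#' physiologically plausible biometry ranges, a driving-standard limit on
#' postoperative corrected acuity, an astigmatism cap, a minimum recovery
#' interval, and per-field keyword lists flagging non-standard surgery,
#' ocular pathology, and previous refractive surgery. The shipped keyword
#' lists are Czech clinical terminology; any list can be replaced.
#'
#' @param acd_range,al_range,k_range,age_range,iol_range numeric length-2
#'   inclusive bounds.
#' @param astig_max_d maximum preoperative corneal astigmatism (D).
#' @param cdva_post_max maximum postoperative CDVA (logMAR; lower is better).
#' @param days_postop_min earliest accepted outcome measurement (days).
#' @param udva_cdva_strict if TRUE uncorrected acuity must be strictly worse
#'   than corrected; default FALSE accepts equality (clinically common).
#' @param keywords named list with character vectors `surgery`, `finding`,
#'   `diagnosis`; case-insensitive substring matches exclude the record.
#' @return a list of class `filter_criteria`.
#' @export
filter_criteria <- function(acd_range = c(1, 5),
                            al_range = c(15, 40),
                            k_range = c(30, 60),
                            age_range = c(18, 99),
                            iol_range = c(6, 35),
                            astig_max_d = 3.0,
                            cdva_post_max = 0.3,
                            days_postop_min = 25,
                            udva_cdva_strict = FALSE,
                            keywords = default_keyword_lists()) {
  structure(
    list(
      acd_range = acd_range, al_range = al_range, k_range = k_range,
      age_range = age_range, iol_range = iol_range,
      astig_max_d = astig_max_d, cdva_post_max = cdva_post_max,
      days_postop_min = days_postop_min,
      udva_cdva_strict = udva_cdva_strict,
      keywords = keywords
    ),
    class = "filter_criteria"
  )
}

#' @rdname filter_criteria
#' @export
default_keyword_lists <- function() {
  list(
    surgery = c("ruptura", "fenestrum", "vitrektom", "praskl", "sklivec",
                "prolaps", "explant", "sulc", "sulk", "rzp", "key hole"),
    finding = c("otok", "striat", "edem", "odchl\u00edpen", "PEX", "jizv",
                "amok", "apar\u00e1t", "defekt", "degener", "endotelopati",
                "fibrin", "guttat", "haze", "hemoftalm", "hemophtalm",
                "luxov", "membr\u00e1n", "precip", "zonul"),
    diagnosis = c("LASIK", "LASEK", "PRK", "LASER", "RELEX", "DMEK",
                  "DALK", "PKP")
  )
}

#' Keyword exclusion check for one or more cases
#'
#' Case-insensitive fixed-substring search of each free-text field against
#' its keyword list; the first matching term is reported.
#'
#' @param surgery_text,finding_text,diagnosis_text character vectors
#'   (NA or "" never match).
#' @param keywords per-field keyword lists as in [default_keyword_lists()].
#' @return data.frame with logical `excluded` and character `matched_term`
#'   (NA when retained).
#' @export
keyword_exclusion <- function(surgery_text = "", finding_text = "",
                              diagnosis_text = "",
                              keywords = default_keyword_lists()) {
  n <- max(length(surgery_text), length(finding_text), length(diagnosis_text))
  fields <- list(
    surgery = rep_len(as.character(surgery_text), n),
    finding = rep_len(as.character(finding_text), n),
    diagnosis = rep_len(as.character(diagnosis_text), n)
  )
  matched <- rep(NA_character_, n)
  for (f in names(fields)) {
    txt <- tolower(ifelse(is.na(fields[[f]]), "", fields[[f]]))
    for (term in keywords[[f]]) {
      hit <- is.na(matched) & grepl(tolower(term), txt, fixed = TRUE)
      matched[hit] <- term
    }
  }
  data.frame(excluded = !is.na(matched), matched_term = matched,
             stringsAsFactors = FALSE)
}

mandatory_numeric_fields <- c("age_years", "k_d", "acd_mm", "al_mm",
                              "rx_pre_d", "iol_implanted_d", "rx_post_d")

# mark still-retained rows failing `bad` with `reason` (scalar or per-row);
# first failure wins
mark_excluded <- function(reason_vec, bad, reason) {
  hit <- is.na(reason_vec) & bad & !is.na(bad)
  reason_vec[hit] <- if (length(reason) == 1) reason else reason[hit]
  reason_vec
}

#' Apply per-record inclusion/exclusion filters
#'
#' Filters are applied in a fixed documented order - completeness, biometry
#' and demographic ranges, follow-up interval, acuity consistency,
#' postoperative CDVA, astigmatism, keyword exclusion - and the first
#' failing rule is recorded as the exclusion reason. Filtering never raises
#' on data content; every input case ends up retained or excluded with
#' exactly one reason.
#'
#' @param cohort data.frame of surgical cases (see [read_cohort_csv()] for
#'   the column contract). May already carry an `exclusion_reason` column
#'   from an earlier stage; those cases keep their reason.
#' @param criteria a [filter_criteria()] object.
#' @return the cohort with an `exclusion_reason` column (NA = retained).
#' @export
apply_record_filters <- function(cohort, criteria = filter_criteria()) {
  reason <- if ("exclusion_reason" %in% names(cohort)) {
    as.character(cohort$exclusion_reason)
  } else {
    rep(NA_character_, nrow(cohort))
  }

  incomplete <- Reduce(`|`, lapply(mandatory_numeric_fields, function(f) {
    if (!f %in% names(cohort)) rep(TRUE, nrow(cohort)) else !is.finite(cohort[[f]])
  }))
  reason <- mark_excluded(reason, incomplete, "incomplete")

  in_range <- function(x, b) x < b[1] | x > b[2]
  reason <- mark_excluded(reason, in_range(cohort$acd_mm, criteria$acd_range), "ACD range")
  reason <- mark_excluded(reason, in_range(cohort$al_mm, criteria$al_range), "AL range")
  reason <- mark_excluded(reason, in_range(cohort$k_d, criteria$k_range), "K range")
  reason <- mark_excluded(reason, in_range(cohort$age_years, criteria$age_range), "age range")
  reason <- mark_excluded(reason, in_range(cohort$iol_implanted_d, criteria$iol_range), "IOL range")

  if ("days_postop" %in% names(cohort)) {
    reason <- mark_excluded(reason, cohort$days_postop < criteria$days_postop_min,
                            "days postop")
  }

  # uncorrected acuity should be no better than corrected (logMAR: larger = worse)
  cmp <- if (criteria$udva_cdva_strict) `<=` else `<`
  if (all(c("udva_pre", "cdva_pre") %in% names(cohort))) {
    reason <- mark_excluded(reason, cmp(cohort$udva_pre, cohort$cdva_pre),
                            "acuity order")
  }
  if (all(c("udva_post", "cdva_post") %in% names(cohort))) {
    reason <- mark_excluded(reason, cmp(cohort$udva_post, cohort$cdva_post),
                            "acuity order")
  }
  if ("cdva_post" %in% names(cohort)) {
    reason <- mark_excluded(reason, cohort$cdva_post > criteria$cdva_post_max,
                            "postop CDVA")
  }
  if ("astig_pre_d" %in% names(cohort)) {
    reason <- mark_excluded(reason, cohort$astig_pre_d > criteria$astig_max_d,
                            "astigmatism")
  }

  kw <- keyword_exclusion(
    cohort$surgery_text %||% "", cohort$finding_text %||% "",
    cohort$diagnosis_text %||% "", criteria$keywords
  )
  reason <- mark_excluded(reason, kw$excluded,
                          ifelse(is.na(kw$matched_term), "keyword",
                                 paste0("keyword:", kw$matched_term)))

  cohort$exclusion_reason <- reason
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exclude fellow-eye pairs with discordant axial lengths
#'
#' When a patient contributes both eyes and their axial lengths differ by
#' more than `max_diff_mm`, both eyes are excluded (a likely measurement
#' error or pathological asymmetry). Single-eye patients are unaffected.
#'
#' @param cohort filtered cohort (rows with non-NA `exclusion_reason` are
#'   ignored and passed through).
#' @param max_diff_mm maximum tolerated inter-eye AL difference (mm).
#' @return cohort with updated `exclusion_reason`.
#' @export
fellow_eye_al_filter <- function(cohort, max_diff_mm = 1) {
  if (!"exclusion_reason" %in% names(cohort)) {
    cohort$exclusion_reason <- NA_character_
  }
  keep <- is.na(cohort$exclusion_reason)
  idx <- which(keep)
  tab <- table(cohort$patient_id[idx])
  if (any(tab > 2)) {
    stop("more than two eyes recorded for patient(s): ",
         paste(names(tab)[tab > 2], collapse = ", "), call. = FALSE)
  }
  pairs <- names(tab)[tab == 2]
  for (p in pairs) {
    rows <- idx[cohort$patient_id[idx] == p]
    if (abs(diff(cohort$al_mm[rows])) > max_diff_mm) {
      cohort$exclusion_reason[rows] <- "fellow-eye AL"
    }
  }
  cohort
}

#' Exclude outliers by the k-sigma rule
#'
#' Single pass: for each listed variable the mean and sample standard
#' deviation are computed over currently retained cases, and any case lying
#' strictly more than `k` standard deviations from the mean in any variable
#' is excluded. Cases exactly at the boundary are retained. Zero-variance
#' variables are skipped with a warning.
#'
#' @param cohort filtered cohort.
#' @param variables columns screened (defaults: the five predictors plus
#'   postoperative refraction).
#' @param k sigma multiplier (default 3).
#' @return cohort with updated `exclusion_reason`.
#' @export
sigma_filter <- function(cohort,
                         variables = c("k_d", "acd_mm", "al_mm", "age_years",
                                       "rx_pre_d", "rx_post_d"),
                         k = 3) {
  if (!"exclusion_reason" %in% names(cohort)) {
    cohort$exclusion_reason <- NA_character_
  }
  idx <- which(is.na(cohort$exclusion_reason))
  if (length(idx) < 3) stop("need at least 3 retained cases", call. = FALSE)
  reason <- cohort$exclusion_reason
  for (v in variables) {
    x <- cohort[[v]][idx]
    m <- mean(x); s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning("sigma_filter: zero variance in ", v, ", skipped")
      next
    }
    bad <- abs(cohort[[v]] - m) > k * s
    keep_mask <- is.na(reason)
    hit <- keep_mask & bad
    reason[hit] <- paste0("sigma:", v)
  }
  cohort$exclusion_reason <- reason
  cohort
}

#' Retained cases of a cohort
#' @param cohort data.frame with an `exclusion_reason` column.
#' @return rows with no exclusion reason.
#' @export
retained <- function(cohort) {
  if (!"exclusion_reason" %in% names(cohort)) return(cohort)
  cohort[is.na(cohort$exclusion_reason), , drop = FALSE]
}

#' Random selection/verification split
#'
#' Uniform case-level split without replacement; deterministic for a fixed
#' seed. The selection count is `round(fraction * n)`.
#'
#' @param cohort data.frame of retained cases.
#' @param selection_fraction fraction in (0, 1) assigned to the selection set.
#' @param seed integer seed for the split.
#' @return list with `selection` and `verification` data.frames.
#' @export
split_cohort <- function(cohort, selection_fraction = 0.7, seed) {
  n <- nrow(cohort)
  if (n == 0) stop("empty cohort", call. = FALSE)
  if (!(selection_fraction > 0 && selection_fraction < 1)) {
    stop("selection_fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  n_sel <- round(selection_fraction * n)
  n_sel <- min(max(n_sel, 1), n - 1)
  sel_idx <- sort(sample.int(n, n_sel))
  list(
    selection = cohort[sel_idx, , drop = FALSE],
    verification = cohort[-sel_idx, , drop = FALSE]
  )
}

#' Fit a [-1, 1] min-max normalizer
#'
#' Stores per-variable minima and maxima over the fitting table; the forward
#' transform maps the column minimum to -1 and the maximum to +1
#' (the `mapminmax` convention).
#'
#' @param table data.frame with the variables to normalize.
#' @param variables columns to include.
#' @return object of class `minmax_normalizer`.
#' @export
fit_normalizer <- function(table, variables = names(table)) {
  mins <- vapply(variables, function(v) min(table[[v]]), numeric(1))
  maxs <- vapply(variables, function(v) max(table[[v]]), numeric(1))
  if (any(!is.finite(mins)) || any(!is.finite(maxs))) {
    stop("non-finite values in normalization fit", call. = FALSE)
  }
  if (any(maxs <= mins)) {
    stop("constant column(s): ",
         paste(variables[maxs <= mins], collapse = ", "), call. = FALSE)
  }
  structure(list(variables = variables, min = mins, max = maxs),
            class = "minmax_normalizer")
}

#' @rdname fit_normalizer
#' @param x data.frame (columns matched by name) or numeric vector with
#'   `variable` naming the column parameters to use.
#' @param normalizer fitted `minmax_normalizer`.
#' @param variable required when `x` is a bare numeric vector.
#' @export
normalize <- function(x, normalizer, variable = NULL) {
  tf <- function(v, var) {
    2 * (v - normalizer$min[[var]]) /
      (normalizer$max[[var]] - normalizer$min[[var]]) - 1
  }
  if (is.data.frame(x)) {
    for (v in intersect(normalizer$variables, names(x))) x[[v]] <- tf(x[[v]], v)
    x
  } else {
    tf(x, variable)
  }
}

#' @rdname fit_normalizer
#' @export
denormalize <- function(x, normalizer, variable = NULL) {
  tf <- function(v, var) {
    (v + 1) / 2 * (normalizer$max[[var]] - normalizer$min[[var]]) +
      normalizer$min[[var]]
  }
  if (is.data.frame(x)) {
    for (v in intersect(normalizer$variables, names(x))) x[[v]] <- tf(x[[v]], v)
    x
  } else {
    tf(x, variable)
  }
}

#' Remove verification cases outside the training range
#'
#' Cases with any listed variable strictly outside the closed interval
#' [min, max] learned from the selection set are removed (extrapolation on
#' non-trained data is not evaluated); boundary values are retained.
#'
#' @param table verification data.frame (raw scale).
#' @param normalizer normalizer fitted on the selection set.
#' @param variables variables checked (default: predictors known to the
#'   normalizer that are present in the table).
#' @return list with `table` (rows in range) and `removed` (rows dropped,
#'   with a `removal_reason` column).
#' @export
clear_out_of_range <- function(table, normalizer,
                               variables = intersect(normalizer$variables,
                                                     names(table))) {
  out <- rep(FALSE, nrow(table))
  why <- rep(NA_character_, nrow(table))
  for (v in variables) {
    bad <- table[[v]] < normalizer$min[[v]] | table[[v]] > normalizer$max[[v]]
    why[bad & !out] <- paste0("out-of-range:", v)
    out <- out | bad
  }
  removed <- table[out, , drop = FALSE]
  if (nrow(removed) > 0) removed$removal_reason <- why[out]
  list(table = table[!out, , drop = FALSE], removed = removed)
}

predictor_vars <- c("k_d", "acd_mm", "al_mm", "age_years", "rx_pre_d")

#' Derive per-eye training targets from surgical outcomes
#'
#' For each retained case: the SRK/T ELP is computed from K and AL, the
#' eye-specific refraction change per 0.5 D of IOL power is evaluated at the
#' implanted power, and the ideal lens power (the training target) follows
#' from the implanted power and the achieved refraction. Optics failures
#' are reported with the offending eye id.
#'
#' @param cohort retained surgical cases.
#' @param consts an [optics_constants()] object.
#' @param normalizer optional fitted normalizer; when supplied, predictors
#'   and the target are returned on the [-1, 1] scale.
#' @return data.frame with `eye_id`, the five predictors, `elp_mm`,
#'   `rx_05iol_d`, `iol_implanted_d`, `rx_post_d`, and the target
#'   `iol_ideal_d`.
#' @export
build_training_table <- function(cohort, consts = optics_constants(),
                                 normalizer = NULL) {
  res <- tryCatch({
    s <- srkt_elp(cohort$k_d, cohort$al_mm, consts)
    r05 <- rx_05iol(cohort$k_d, cohort$al_mm, s$elp_mm,
                    cohort$iol_implanted_d, consts)
    ideal <- iol_ideal(cohort$iol_implanted_d, cohort$rx_post_d, r05)
    list(elp = s$elp_mm, r05 = r05, ideal = ideal)
  }, error = function(e) {
    stop("target derivation failed (eyes ",
         paste(utils::head(cohort$eye_id, 3), collapse = ", "),
         " ...): ", conditionMessage(e), call. = FALSE)
  })
  tab <- data.frame(
    eye_id = cohort$eye_id,
    cohort[, predictor_vars, drop = FALSE],
    elp_mm = res$elp, rx_05iol_d = res$r05,
    iol_implanted_d = cohort$iol_implanted_d,
    rx_post_d = cohort$rx_post_d,
    iol_ideal_d = res$ideal,
    stringsAsFactors = FALSE
  )
  if (!is.null(normalizer)) tab <- normalize(tab, normalizer)
  tab
}

#' Run the full preparation stage
#'
#' Chains the filters in the documented order (record filters, fellow-eye
#' filter, sigma filter), derives targets, splits into selection and
#' verification sets, fits the min-max normalizer on the selection set, and
#' clears verification cases outside the trained range.
#'
#' @param cohort raw cohort data.frame.
#' @param criteria a [filter_criteria()] object.
#' @param consts an [optics_constants()] object.
#' @param selection_fraction selection-set share (default 0.7).
#' @param seed integer seed for the split.
#' @return list with `cohort` (with exclusion reasons), `selection`,
#'   `verification` (raw-scale tables with targets), `normalizer`,
#'   `selection_norm`, `verification_norm` (normalized tables), and
#'   `out_of_range` (verification rows removed).
#' @export
prepare_cohort <- function(cohort, criteria = filter_criteria(),
                           consts = optics_constants(),
                           selection_fraction = 0.7, seed = 1L) {
  cohort <- apply_record_filters(cohort, criteria)
  cohort <- fellow_eye_al_filter(cohort)
  cohort <- sigma_filter(cohort)
  tab <- build_training_table(retained(cohort), consts)
  parts <- split_cohort(tab, selection_fraction, seed = seed)
  norm <- fit_normalizer(parts$selection,
                         variables = c(predictor_vars, "iol_ideal_d"))
  cleared <- clear_out_of_range(parts$verification, norm,
                                variables = predictor_vars)
  list(
    cohort = cohort,
    selection = parts$selection,
    verification = cleared$table,
    out_of_range = cleared$removed,
    normalizer = norm,
    selection_norm = normalize(parts$selection, norm),
    verification_norm = normalize(cleared$table, norm)
  )
}
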