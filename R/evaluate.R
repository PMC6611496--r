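#' Prediction-error summary statistics
#'
#' Mean signed error, mean/median absolute error, sample standard
#' deviation, extremes, and the percentage of eyes within each error
#' threshold. "Within +/-t" uses the closed interval |e| <= t (the common
#' convention in refractive outcome reporting); set `strict = TRUE` for the
#' open interval.
#'
#' @param errors numeric vector of signed prediction errors (D).
#' @param thresholds error thresholds in D.
#' @param strict use |e| < t instead of |e| <= t.
#' @return list of class `pe_summary` with `me`, `mae`, `medae`, `std`,
#'   `min`, `max`, `pct_within` (named vector, percent), `n`.
#' @export
pe_summary <- function(errors, thresholds = c(0.25, 0.50, 0.75, 1.00),
                       strict = FALSE) {
  if (length(errors) == 0) stop("empty error vector", call. = FALSE)
  cmp <- if (strict) `<` else `<=`
  pct <- vapply(thresholds,
                function(t) 100 * mean(cmp(abs(errors), t)), numeric(1))
  names(pct) <- sprintf("±%.2f", thresholds)
  structure(
    list(me = mean(errors), mae = mean(abs(errors)),
         medae = stats::median(abs(errors)), std = stats::sd(errors),
         min = min(errors), max = max(errors),
         pct_within = pct, n = length(errors)),
    class = "pe_summary"
  )
}

#' @export
print.pe_summary <- function(x, ...) {
  cat(sprintf("n = %d eyes\n", x$n))
  cat(sprintf("ME %7.3f  MAE %6.3f  MedAE %6.3f  Std %6.3f  [%.3f, %.3f]\n",
              x$me, x$mae, x$medae, x$std, x$min, x$max))
  cat("within:", paste(sprintf("%s %.1f%%", names(x$pct_within),
                               x$pct_within), collapse = "  "), "\n")
  invisible(x)
}

#' Axial-length subgroup assignment
#'
#' SHORT: AL <= 22 mm; MEDIUM: 22 < AL < 24 mm; LONG: AL >= 24 mm. The
#' three subgroups partition the cohort; ALL is their union.
#'
#' @param al_mm axial lengths (mm).
#' @return factor with levels SHORT, MEDIUM, LONG.
#' @export
al_subgroups <- function(al_mm) {
  factor(ifelse(al_mm <= 22, "SHORT", ifelse(al_mm < 24, "MEDIUM", "LONG")),
         levels = c("SHORT", "MEDIUM", "LONG"))
}

#' Per-eye refractive prediction errors for every method
#'
#' The clinical-results (CR) error is the achieved postoperative refraction
#' itself (target refraction was emmetropia); each model's error is the
#' residual refraction back-calculated from its predicted lens power. Eyes
#' missing a prediction are dropped with a warning.
#'
#' @param verification data.frame with `eye_id`, `al_mm`,
#'   `iol_implanted_d`, `rx_post_d`, `rx_05iol_d` (as produced by
#'   [build_training_table()]).
#' @param predictions named list of numeric vectors, one predicted IOL
#'   power (D) per eye per model.
#' @return data.frame: `eye_id`, `al_mm`, `subgroup`, `CR`, one column per
#'   model.
#' @export
refractive_error_table <- function(verification, predictions = list()) {
  out <- data.frame(
    eye_id = verification$eye_id,
    al_mm = verification$al_mm,
    subgroup = al_subgroups(verification$al_mm),
    CR = verification$rx_post_d,
    stringsAsFactors = FALSE
  )
  keep <- rep(TRUE, nrow(out))
  for (m in names(predictions)) {
    p <- predictions[[m]]
    stopifnot(length(p) == nrow(verification))
    keep <- keep & is.finite(p)
    out[[m]] <- rx_predicted(verification$iol_implanted_d, p,
                             verification$rx_05iol_d,
                             verification$rx_post_d)
  }
  if (!all(keep)) {
    warning(sum(!keep), " eye(s) dropped for missing predictions")
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Full evaluation report across methods and axial-length subgroups
#'
#' For every subgroup (SHORT/MEDIUM/LONG and ALL) and method, a
#' [pe_summary()]; and for every method pair, the paired-test battery:
#' Wilcoxon signed-rank on absolute errors, and McNemar (Yates) plus the
#' sign test on the within-threshold indicators at each threshold.
#' Bonferroni-adjusted p-values are reported with the family size `m`
#' (the number of comparisons emitted per subgroup table). Subgroups with
#' fewer than `min_n` eyes get a summary but no tests.
#'
#' @param error_table output of [refractive_error_table()].
#' @param methods method columns to evaluate (default: all non-key
#'   columns).
#' @param thresholds PE thresholds in D.
#' @param min_n smallest subgroup size for which tests are run.
#' @return list of class `evaluation_report` with `summaries` (data.frame)
#'   and `tests` (data.frame).
#' @export
evaluation_report <- function(error_table,
                              methods = setdiff(names(error_table),
                                                c("eye_id", "al_mm",
                                                  "subgroup")),
                              thresholds = c(0.25, 0.50, 0.75, 1.00),
                              min_n = 5) {
  groups <- c(as.list(split(seq_len(nrow(error_table)),
                            error_table$subgroup)),
              list(ALL = seq_len(nrow(error_table))))

  summaries <- list()
  tests <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (length(idx) == 0) next
    for (m in methods) {
      s <- pe_summary(error_table[[m]][idx], thresholds)
      summaries[[length(summaries) + 1]] <- data.frame(
        subgroup = g, method = m, n = s$n, me = s$me, mae = s$mae,
        medae = s$medae, std = s$std, min = s$min, max = s$max,
        t(s$pct_within), check.names = FALSE
      )
    }
    if (length(idx) < min_n) {
      message("subgroup ", g, ": n = ", length(idx), " < ", min_n,
              ", tests skipped")
      next
    }
    if (length(methods) < 2) next
    pairs <- utils::combn(methods, 2, simplify = FALSE)
    grows <- list()
    for (pr in pairs) {
      ea <- error_table[[pr[1]]][idx]
      eb <- error_table[[pr[2]]][idx]
      wt <- wilcoxon_paired(abs(ea), abs(eb))
      grows[[length(grows) + 1]] <- data.frame(
        subgroup = g, comparison = paste(pr, collapse = " vs "),
        test = "wilcoxon", threshold = NA_real_,
        statistic = wt$statistic, p_value = wt$p_value
      )
      for (t in thresholds) {
        ia <- abs(ea) <= t; ib <- abs(eb) <= t
        mn <- suppressWarnings(mcnemar_yates(ia, ib))
        st <- suppressWarnings(sign_test(as.numeric(ia), as.numeric(ib)))
        grows[[length(grows) + 1]] <- data.frame(
          subgroup = g, comparison = paste(pr, collapse = " vs "),
          test = "mcnemar", threshold = t,
          statistic = mn$statistic, p_value = mn$p_value
        )
        grows[[length(grows) + 1]] <- data.frame(
          subgroup = g, comparison = paste(pr, collapse = " vs "),
          test = "sign", threshold = t,
          statistic = st$positive, p_value = st$p_value
        )
      }
    }
    gtab <- do.call(rbind, grows)
    gtab$m <- nrow(gtab)
    gtab$p_adjusted <- bonferroni(gtab$p_value, m = nrow(gtab))
    tests[[length(tests) + 1]] <- gtab
  }
  structure(
    list(
      summaries = do.call(rbind, summaries),
      tests = if (length(tests)) do.call(rbind, tests) else NULL
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Prediction-error summaries:\n")
  print(x$summaries, digits = 3, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nPaired tests (Bonferroni family size m per subgroup):\n")
    print(x$tests, digits = 3, row.names = FALSE)
  }
  invisible(x)
}
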