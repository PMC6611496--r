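cohort_numeric_cols <- c("age_years", "k_d", "acd_mm", "al_mm", "rx_pre_d",
                         "iol_implanted_d", "rx_post_d", "udva_pre",
                         "cdva_pre", "udva_post", "cdva_post", "astig_pre_d",
                         "days_postop")
cohort_text_cols <- c("eye_id", "patient_id", "eye", "surgery_text",
                      "finding_text", "diagnosis_text")

#' Read a per-eye surgical cohort from CSV
#'
#' One flat dialect: comma-separated, UTF-8, decimal point, mandatory
#' header. Mandatory columns: `eye_id`, `patient_id`, `eye`, the five
#' predictors (`age_years`, `k_d`, `acd_mm`, `al_mm`, `rx_pre_d`),
#' `iol_implanted_d` and `rx_post_d`. Optional columns (acuities,
#' astigmatism, follow-up days, free-text fields) are filled with NA when
#' absent; empty numeric cells become NA (triggering the "incomplete"
#' filter downstream); malformed numerics are rejected with their row
#' numbers. Czech-style decimal commas are rejected explicitly.
#'
#' @param path CSV file path.
#' @return cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  mandatory <- c("eye_id", "patient_id", "eye", "age_years", "k_d",
                 "acd_mm", "al_mm", "rx_pre_d", "iol_implanted_d",
                 "rx_post_d")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- raw
  for (col in intersect(cohort_numeric_cols, names(raw))) {
    v <- trimws(raw[[col]])
    if (any(grepl(",", v, fixed = TRUE))) {
      stop("column ", col, ": decimal commas found; the dialect requires ",
           "a decimal point", call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(num))
    if (length(bad)) {
      stop("column ", col, ": malformed numeric value(s) in row(s) ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
    out[[col]] <- num
  }
  for (col in setdiff(cohort_numeric_cols, names(out))) out[[col]] <- NA_real_
  for (col in setdiff(cohort_text_cols, names(out))) out[[col]] <- ""
  out
}

#' @rdname read_cohort_csv
#' @param cohort cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Import a per-eye refraction table for evaluation-only mode
#'
#' Reads a deposited per-eye refraction outcome table (one row per eye:
#' axial-length subgroup plus the achieved or back-calculated refraction of
#' each method) and maps its columns onto the evaluation contract, so
#' outcome summaries and paired tests can be reproduced without biometry
#' or trained models. The default mapping matches the layout of published
#' per-eye outcome supplements (subgroup label column plus one refraction
#' column per method).
#'
#' @param path CSV path.
#' @param mapping named character vector: names are output columns
#'   (`subgroup` plus method names), values are input column labels.
#' @return data.frame with `eye_id`, `subgroup` (factor SHORT/MEDIUM/LONG)
#'   and one numeric error column per method, ready for
#'   [evaluation_report()].
#' @export
read_refraction_csv <- function(path,
                                mapping = c(subgroup = "SUBGROUP (AL)",
                                            CR = "CR",
                                            `SVM-RM` = "SVM-RM",
                                            `MLNN-EM` = "ANN-EM")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(unname(mapping), names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(eye_id = sprintf("E%05d", seq_len(nrow(raw))),
                    stringsAsFactors = FALSE)
  for (nm in names(mapping)) {
    v <- raw[[mapping[[nm]]]]
    out[[nm]] <- if (nm == "subgroup") {
      factor(toupper(trimws(v)), levels = c("SHORT", "MEDIUM", "LONG"))
    } else {
      as.numeric(v)
    }
  }
  out
}

#' Write an evaluation report to disk
#'
#' Emits `summaries.csv`, `tests.csv` and a combined `report.json` into
#' `dir`.
#'
#' @param report an [evaluation_report()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("summaries.csv", "tests.csv", "report.json"))
  utils::write.csv(report$summaries, paths[1], row.names = FALSE)
  if (!is.null(report$tests)) {
    utils::write.csv(report$tests, paths[2], row.names = FALSE)
  }
  jsonlite::write_json(
    list(summaries = report$summaries, tests = report$tests),
    paths[3], dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(paths)
}

#' Bundle of all pipeline settings
#'
#' Collects the optics constants, filter criteria, split settings, model
#' configurations, evaluation thresholds and generator settings into one
#' serializable object, so a saved configuration plus the master seed
#' reproduces a run.
#'
#' @param optics [optics_constants()].
#' @param filters [filter_criteria()].
#' @param selection_fraction selection-set share.
#' @param seed master seed.
#' @param svm [svm_config()].
#' @param mlnn [mlnn_config()].
#' @param thresholds evaluation PE thresholds (D).
#' @param synthetic [synthetic_config()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(optics = optics_constants(),
                            filters = filter_criteria(),
                            selection_fraction = 0.7,
                            seed = 1L,
                            svm = svm_config(seed = derive_seed(seed, "svm")),
                            mlnn = mlnn_config(seed = derive_seed(seed, "mlnn")),
                            thresholds = c(0.25, 0.50, 0.75, 1.00),
                            synthetic = synthetic_config(seed = seed)) {
  structure(
    list(optics = optics, filters = filters,
         selection_fraction = selection_fraction, seed = as.integer(seed),
         svm = svm, mlnn = mlnn, thresholds = thresholds,
         synthetic = synthetic),
    class = "pipeline_config"
  )
}
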