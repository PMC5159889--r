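# Delimited-text interfaces: long-format choices, participant covariates,
# cohort configuration, and report export.

#' Read / write long-format choice records
#'
#' The on-disk layout has one row per observed decision with columns
#' `participant_id`, `trial_id`, `lottery_amount_usd`,
#' `lottery_probability`, `safe_amount_usd`, `chose_lottery` (0/1).
#'
#' @param path CSV file path.
#' @return `read_choices`: a records data frame in the package's internal
#'   column naming.
#' @export
read_choices <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "trial_id", "lottery_amount_usd",
              "lottery_probability", "safe_amount_usd", "chose_lottery")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("choices file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  data.frame(participant_id = as.character(raw$participant_id),
             trial_id = raw$trial_id,
             lottery_amount = raw$lottery_amount_usd,
             lottery_probability = raw$lottery_probability,
             safe_amount = raw$safe_amount_usd,
             chose_lottery = as.integer(raw$chose_lottery))
}

#' @rdname read_choices
#' @param records Records data frame (internal naming).
#' @export
write_choices <- function(records, path) {
  stop_if_not_records(records)
  out <- data.frame(participant_id = records$participant_id,
                    trial_id = records$trial_id,
                    lottery_amount_usd = records$lottery_amount,
                    lottery_probability = records$lottery_probability,
                    safe_amount_usd = records$safe_amount,
                    chose_lottery = as.integer(records$chose_lottery))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read / write participant covariates
#'
#' Columns: `participant_id`, `age_years`, `gender`, `rppc_gmv`,
#' `global_gmv`.
#'
#' @param path CSV file path.
#' @export
read_participants <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "age_years", "gender", "rppc_gmv",
              "global_gmv")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("participants file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  data.frame(participant_id = as.character(raw$participant_id),
             age = raw$age_years, gender = raw$gender,
             rppc_gmv = raw$rppc_gmv, global_gmv = raw$global_gmv)
}

#' @rdname read_participants
#' @param participants Participant covariate table (internal naming).
#' @export
write_participants <- function(participants, path) {
  out <- data.frame(participant_id = participants$participant_id,
                    age_years = participants$age,
                    gender = participants$gender,
                    rppc_gmv = participants$rppc_gmv,
                    global_gmv = participants$global_gmv)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort configuration from YAML or JSON
#'
#' Any subset of [cohort_config()] fields may be given; the rest take their
#' defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json", call. = FALSE)
  }
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(vals$true_coefficients)) {
    vals$true_coefficients <- unlist(vals$true_coefficients)
  }
  do.call(cohort_config, vals)
}

#' Write an analysis report to disk
#'
#' Exports the coefficient table (`fits.csv`), model summaries
#' (`models.json`), exclusion log (`exclusions.csv`), model-free regression
#' (`model_free.csv`), individual fits (`individual_fits.csv`) and the
#' added-variable plot data (`partial_plots.csv`) to a directory.
#'
#' @param report A `risk_analysis_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "risk_analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$coefficient_table,
                   file.path(dir, "fits.csv"), row.names = FALSE)
  utils::write.csv(report$exclusions,
                   file.path(dir, "exclusions.csv"), row.names = FALSE)
  utils::write.csv(report$model_free,
                   file.path(dir, "model_free.csv"), row.names = FALSE)
  if (!is.null(report$individual_fits)) {
    utils::write.csv(report$individual_fits,
                     file.path(dir, "individual_fits.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$partial_plots)) {
    utils::write.csv(report$partial_plots,
                     file.path(dir, "partial_plots.csv"), row.names = FALSE)
  }
  models <- list(bic = report$bic_table, meta = report$meta)
  jsonlite::write_json(models, file.path(dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
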