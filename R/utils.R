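# internal helpers shared across modules

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
# seed = NULL means "use the ambient stream" (needed so generate_cohort can
# drive all stages from one seed).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if_not_records <- function(records) {
  needed <- c("participant_id", "trial_id", "lottery_amount",
              "lottery_probability", "safe_amount", "chose_lottery")
  if (!is.data.frame(records)) {
    stop("`records` must be a data frame of choice records", call. = FALSE)
  }
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("`records` is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(records)
}
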