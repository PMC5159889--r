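#' Default lottery amount grid
#'
#' The risky-choice task crosses 20 monetary amounts spanning $5--$120 with
#' three payout probabilities. The exact interior amounts are configurable;
#' the default is an approximately log-spaced integer grid from $5 to $120
#' inclusive. Estimation results should not (and, in the recovery suites, do
#' not) depend on the exact interior spacing.
#'
#' @return Integer vector of 20 dollar amounts.
#' @export
default_amount_grid <- function() {
  c(5, 6, 7, 8, 10, 12, 14, 16, 19, 23, 27, 31, 37, 44, 52, 61, 73, 86,
    101, 120)
}

#' Construct the risky choice set
#'
#' Builds the full factorial crossing of lottery amounts and payout
#' probabilities against a fixed certain amount. The default configuration
#' (20 amounts x 3 probabilities, $5 safe) yields the 60-trial design.
#' Trials are ordered deterministically by (probability, amount); use
#' [shuffle_trials()] for per-participant random orders.
#'
#' @param amounts Numeric vector of unique, positive lottery amounts (USD).
#' @param probabilities Numeric vector of unique payout probabilities in
#'   (0, 1).
#' @param safe_amount Certain amount offered against every lottery (USD).
#' @return A `choice_set` data frame with columns `trial_id`,
#'   `lottery_amount`, `lottery_probability`, `safe_amount`, `is_dominated`.
#' @examples
#' cs <- build_choice_set()
#' nrow(cs)            # 60
#' sum(cs$is_dominated) # 3: the $5 lottery at each probability
#' @export
build_choice_set <- function(amounts = default_amount_grid(),
                             probabilities = c(0.25, 0.5, 0.75),
                             safe_amount = 5) {
  if (length(amounts) == 0L || anyNA(amounts) || any(amounts <= 0)) {
    stop("`amounts` must be non-empty and strictly positive", call. = FALSE)
  }
  if (anyDuplicated(amounts)) {
    stop("`amounts` must be unique", call. = FALSE)
  }
  if (length(probabilities) == 0L || anyNA(probabilities) ||
      any(probabilities <= 0 | probabilities >= 1)) {
    stop("`probabilities` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (anyDuplicated(probabilities)) {
    stop("`probabilities` must be unique", call. = FALSE)
  }
  if (length(safe_amount) != 1L || safe_amount <= 0) {
    stop("`safe_amount` must be a single positive amount", call. = FALSE)
  }
  grid <- expand.grid(lottery_amount = sort(amounts),
                      lottery_probability = sort(probabilities),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$lottery_probability, grid$lottery_amount), ]
  out <- data.frame(
    trial_id = seq_len(nrow(grid)),
    lottery_amount = grid$lottery_amount,
    lottery_probability = grid$lottery_probability,
    safe_amount = safe_amount,
    row.names = NULL
  )
  out$is_dominated <- flag_dominated(out$lottery_amount, out$safe_amount)
  class(out) <- c("choice_set", "data.frame")
  out
}

#' Randomize trial order
#'
#' Trial order was randomized independently for each participant in the
#' task; this utility reproduces that, deterministically given a seed.
#'
#' @param choice_set A `choice_set` from [build_choice_set()].
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @return The same rows in permuted order.
#' @export
shuffle_trials <- function(choice_set, seed = NULL) {
  stopifnot(is.data.frame(choice_set), nrow(choice_set) >= 1L)
  perm <- with_seed(seed, sample.int(nrow(choice_set)))
  out <- choice_set[perm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag first-order stochastically dominated lotteries
#'
#' A lottery paying at most the certain amount with probability < 1 is
#' objectively worse than the certain amount; choosing it reveals either a
#' preference for less money or a misunderstanding of the task.
#'
#' @param lottery_amount Numeric vector of lottery amounts.
#' @param safe_amount Certain amount (scalar or vector).
#' @return Logical vector, `TRUE` where the lottery is dominated.
#' @export
flag_dominated <- function(lottery_amount, safe_amount = 5) {
  stopifnot(is.numeric(lottery_amount), is.numeric(safe_amount))
  lottery_amount <= safe_amount
}

#' Participant exclusion rule for dominated choices
#'
#' A participant is excluded when they chose the lottery on strictly more
#' than `threshold` (default 50%) of the dominated trials they faced; risk
#' preferences cannot in principle be estimated for such participants. The
#' rate is computed over dominated trials only, where a preference for less
#' money is actually demonstrable.
#'
#' @param records Choice records for a single participant (data frame with
#'   `lottery_amount`, `safe_amount`, `chose_lottery`).
#' @param threshold Exclusion threshold on the dominated-choice rate;
#'   exclusion requires the rate to exceed it strictly.
#' @return List with `exclude` (logical), `dominated_rate`, `n_dominated`.
#' @export
apply_exclusion <- function(records, threshold = 0.5) {
  stop_if_not_records(records)
  if (length(unique(records$participant_id)) > 1L) {
    stop("`apply_exclusion` expects records from a single participant; ",
         "use `exclusion_log` for a cohort", call. = FALSE)
  }
  dom <- flag_dominated(records$lottery_amount, records$safe_amount)
  if (!any(dom)) {
    stop("no dominated trials present; the exclusion rule is inapplicable",
         call. = FALSE)
  }
  rate <- mean(as.logical(records$chose_lottery[dom]))
  list(exclude = rate > threshold,
       dominated_rate = rate,
       n_dominated = sum(dom))
}

#' Per-participant exclusion log
#'
#' Applies [apply_exclusion()] to every participant in a cohort's records.
#'
#' @param records Choice records for one or more participants.
#' @param threshold Passed to [apply_exclusion()].
#' @return Data frame with one row per participant: `participant_id`,
#'   `dominated_rate`, `n_dominated`, `exclude`.
#' @export
exclusion_log <- function(records, threshold = 0.5) {
  stop_if_not_records(records)
  ids <- unique(records$participant_id)
  rows <- lapply(ids, function(id) {
    res <- apply_exclusion(records[records$participant_id == id, ,
                                   drop = FALSE], threshold = threshold)
    data.frame(participant_id = id,
               dominated_rate = res$dominated_rate,
               n_dominated = res$n_dominated,
               exclude = res$exclude)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Proportion of lottery choices
#'
#' Model-free summary of risk taking: the fraction of trials on which the
#' lottery was chosen. Fewer lottery choices indicate greater risk aversion.
#'
#' @param records Choice records (any number of participants).
#' @return Fraction in [0, 1].
#' @export
proportion_lottery <- function(records) {
  stop_if_not_records(records)
  if (nrow(records) == 0L) {
    stop("cannot compute a proportion from zero records", call. = FALSE)
  }
  mean(as.logical(records$chose_lottery))
}
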