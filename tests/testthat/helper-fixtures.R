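# Shared fixtures: all synthetic, built in code at test time.

# A reduced choice set (8 amounts x 3 probabilities) for fast fits.
small_choice_set <- function() {
  build_choice_set(amounts = c(5, 7, 10, 16, 27, 44, 73, 120))
}

# Hand-built records for one participant: choices supplied explicitly.
records_from_choices <- function(choice_set, chose, id = "P001") {
  stopifnot(length(chose) == nrow(choice_set))
  data.frame(participant_id = id,
             trial_id = choice_set$trial_id,
             lottery_amount = choice_set$lottery_amount,
             lottery_probability = choice_set$lottery_probability,
             safe_amount = choice_set$safe_amount,
             chose_lottery = as.integer(chose))
}

# Quick intercept-only cohort on the reduced choice set.
toy_cohort <- function(n_participants, alpha0 = 0.6, sigma = 1,
                       seed = 101, choice_set = small_choice_set()) {
  participants <- data.frame(participant_id = sprintf("P%03d",
                                                      seq_len(n_participants)))
  records <- simulate_choices(participants, choice_set,
                              c(intercept = alpha0), sigma, seed = seed)
  list(participants = participants, records = records)
}

# Table-derived coefficient sets used as generating truths.
model1_truth <- c(intercept = 0.669, age = -0.003)
model1_sigma <- 1.016
model2_truth <- c(intercept = 0.152, rppc_gmv = 1.338)
model2_sigma <- 0.986
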