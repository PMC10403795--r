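# fixture builders shared across the suite

# a daily_records frame from a steps vector; NA steps = unrecorded days
make_records <- function(steps, start = as.Date("2024-01-01"), worn = NA,
                         recording_failure = FALSE, participant_id = "p1", ...) {
  df <- data.frame(
    date = start + seq_along(steps) - 1,
    steps = steps,
    worn = worn,
    recording_failure = recording_failure,
    ...
  )
  daily_records(df, participant_id = participant_id)
}

# behavior response with all 32 items at `base`, overridden by name
make_behavior <- function(base = 4, ...) {
  scores <- stats::setNames(rep(base, 32), essmbpa_items())
  over <- list(...)
  scores[names(over)] <- unlist(over)
  behavior_response(scores)
}

# independent oracle: two-sided exact signed-rank p by brute-force
# enumeration of all 2^n sign assignments (midranks for tied |d|)
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ws <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
}

tiny_sim_config <- function(...) {
  sim_config(recording_failure_prob = 0, dropout_hazard = 0, ...)
}
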