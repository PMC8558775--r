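# Simulated call-level response tables for the statistics tests: the grouping
# structure of a playback study (sessions of nine randomized blocks, two
# housed seals) with known session/seal random intercepts and an optional
# planted condition effect, without synthesizing audio.
sim_response_table <- function(seed, shift = c(no_playback = 0, low = 0, high = 0),
                               n_sessions = 6, mean_calls = 4,
                               sd_session = 1, sd_seal = 2, sd_res = 10,
                               baseline = 400) {
  set.seed(seed)
  seal_eff <- stats::setNames(rnorm(4, 0, sd_seal), c("A", "B", "C", "D"))
  rows <- list()
  for (s in seq_len(n_sessions)) {
    des <- make_session_design(seed = seed * 1000L + s)
    seals <- if (s <= ceiling(n_sessions / 2)) c("A", "B") else c("C", "D")
    sess_eff <- rnorm(1, 0, sd_session)
    for (b in 1:9) {
      n <- rpois(1, mean_calls)
      if (n == 0) next
      seal <- sample(seals, n, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        session_id = sprintf("S%02d", s), seal_id = seal,
        condition = des$condition[b], trial_index = b,
        y = baseline + shift[[des$condition[b]]] + sess_eff + seal_eff[seal] +
          rnorm(n, 0, sd_res),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

# Exhaustive-enumeration oracle for the two-sided Mann-Whitney p-value:
# every assignment of the pooled observations to the two groups, U computed
# by definition, two-sided p as 2 * min(tail probabilities), capped at 1.
mw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combs <- utils::combn(length(pooled), n)
  u_all <- apply(combs, 2, function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}
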