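test_that("with zero estimated group variance the mixed model collapses to OLS", {
  tab <- sim_response_table(51, sd_session = 0, sd_seal = 0, sd_res = 5)
  # remove any accidental between-group mean structure so the variance
  # estimates sit at the zero boundary: the degenerate limit
  tab$condition <- factor(tab$condition, levels = CONDITIONS)
  fix_fit <- lm(y ~ condition + trial_index, data = tab)
  eps <- resid(lm(resid(fix_fit) ~ session_id + seal_id, data = tab))
  tab$y <- fitted(fix_fit) + eps
  suppressMessages(fit <- fit_random_intercept_model(tab, "y"))
  ols <- lm(y ~ condition + trial_index, data = tab)
  expect_equal(unname(fit$fixef[names(fit$fixef)]),
               unname(coef(ols)[names(fit$fixef)]), tolerance = 1e-6)
})

test_that("variance components are recovered on simulated intercepts", {
  # crossed design with enough levels of both factors: 40 sessions x 20 calls,
  # seals drawn from a pool of 16
  set.seed(52)
  seal_pool <- sprintf("P%02d", 1:16)
  seal_eff <- stats::setNames(rnorm(16, 0, 2), seal_pool)
  rows <- list()
  for (s in 1:40) {
    des <- make_session_design(seed = 5200 + s)
    seals <- sample(seal_pool, 4)
    sess_eff <- rnorm(1, 0, 1)
    for (b in 1:9) {
      n <- if (b <= 2) 3L else 2L
      seal <- sample(seals, n, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        session_id = sprintf("S%02d", s), seal_id = seal,
        condition = des$condition[b], trial_index = b,
        y = 400 + sess_eff + seal_eff[seal] + rnorm(n, 0, 1),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  expect_gte(nrow(tab), 800)
  suppressMessages(fit <- fit_random_intercept_model(tab, "y"))
  expect_equal(unname(fit$varcomp["session_id"]), 1, tolerance = 0.3)
  expect_equal(unname(fit$varcomp["seal_id"]), 4, tolerance = 0.3)
  expect_equal(unname(fit$varcomp["residual"]), 1, tolerance = 0.3)
  expect_gt(fit$lr_stat, -1e-8)
})

test_that("a pure-noise predictor barely moves pseudo-R2", {
  tab <- sim_response_table(53, n_sessions = 20, mean_calls = 5)
  set.seed(99)
  tab$junk <- rnorm(nrow(tab))
  suppressMessages(f0 <- fit_random_intercept_model(tab, "y"))
  suppressMessages(f1 <- fit_random_intercept_model(
    tab, "y", fixed = c("condition", "trial_index", "junk")))
  expect_lt(abs(f1$pseudo_r2 - f0$pseudo_r2), 0.01)
})

test_that("permutation p-values have two-atom support at n_perm = 1", {
  tab <- sim_response_table(54)
  ps <- vapply(1:12, function(i)
    suppressMessages(permutation_p(tab, "y", n_perm = 1, seed = i)$p_perm),
    numeric(1))
  expect_true(all(ps %in% c(0.5, 1.0)))
})

test_that("a strong planted effect reaches the smallest attainable p", {
  hits <- vapply(1:5, function(i) {
    tab <- sim_response_table(540 + i, shift = c(no_playback = 0, low = -25, high = -60),
                              n_sessions = 8)
    suppressMessages(permutation_p(tab, "y", n_perm = 99, seed = i)$p_perm)
  }, numeric(1))
  expect_true(mean(hits == 1 / 100) >= 0.8)
})

test_that("permutation p is invariant to affine response transforms", {
  tab <- sim_response_table(55, shift = c(no_playback = 0, low = -5, high = -12))
  suppressMessages(p1 <- permutation_p(tab, "y", n_perm = 60, seed = 7)$p_perm)
  tab$y <- 3 + 2 * tab$y
  suppressMessages(p2 <- permutation_p(tab, "y", n_perm = 60, seed = 7)$p_perm)
  expect_equal(p1, p2)
})

test_that("the full-refit likelihood-ratio statistic agrees with the fast one", {
  tab <- sim_response_table(56, shift = c(no_playback = 0, low = -15, high = -30),
                            n_sessions = 4, mean_calls = 2)
  suppressMessages(pf <- permutation_p(tab, "y", n_perm = 30, seed = 3,
                                       statistic = "full_lr"))
  suppressMessages(pg <- permutation_p(tab, "y", n_perm = 30, seed = 3))
  expect_lt(pf$p_perm, 0.1)
  expect_lt(pg$p_perm, 0.1)
})

test_that("Mann-Whitney matches hand-derived and enumerated references", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  same <- mann_whitney(1:10 + 0.5, 1:10 + 0.5)
  expect_gte(same$p, 0.99)
  set.seed(61)
  big <- mann_whitney(rnorm(100), rnorm(100) + 1)
  expect_lt(big$p, 0.001)
})

test_that("Mann-Whitney equals the exhaustive enumeration oracle up to n = 8", {
  set.seed(62)
  for (nx in 1:7) {
    ny_max <- 8 - nx
    for (ny in 1:ny_max) {
      x <- round(rnorm(nx), 6); y <- round(rnorm(ny, 0.5), 6)
      expect_equal(mann_whitney(x, y)$p, mw_enum_oracle(x, y),
                   tolerance = 1e-10,
                   info = sprintf("nx=%d ny=%d", nx, ny))
    }
  }
})

test_that("Bonferroni thresholds match the printed constants", {
  expect_equal(round(bonferroni_alpha_pairwise(), 4), 0.0167)
  expect_equal(round(bonferroni_alpha_per_seal(8), 5), 0.00208)
})

test_that("per-seal tests flag a planted Lombard responder only", {
  set.seed(63)
  seals <- LETTERS[1:8]
  rows <- list()
  for (seal in seals) for (cond in CONDITIONS) {
    n <- 40
    mu <- 1e-3
    if (seal == "G" && cond == "high") mu <- mu * 10^(6 / 10)  # +6 dB intensity
    rows[[length(rows) + 1L]] <- data.frame(
      session_id = "S1", seal_id = seal, condition = cond,
      intensity_linear = rlnorm(n, log(mu), 0.5),
      octave_slope_db_per_oct = rnorm(n, -3, 1), r14_db = rnorm(n, 5, 2),
      stringsAsFactors = FALSE)
  }
  feats <- do.call(rbind, rows)
  res <- per_seal_intensity_tests(feats)
  expect_equal(unique(res$alpha_adjusted), 0.05 / 24)
  g_high <- res[res$seal_id == "G" & res$measure == "intensity" &
                  res$comparison == "no_playback_vs_high", ]
  expect_true(g_high$significant)
  others <- res[!(res$seal_id == "G" & res$measure == "intensity"), ]
  expect_lt(mean(others$significant), 0.05)
})

test_that("per-seal tests skip empty condition cells with a message", {
  feats <- data.frame(session_id = "S1", seal_id = "A",
                      condition = c("low", "low", "high", "high"),
                      intensity_linear = c(1, 2, 3, 4),
                      octave_slope_db_per_oct = NA_real_, r14_db = NA_real_)
  expect_message(res <- per_seal_intensity_tests(feats), "empty condition cell")
  expect_true(all(res$comparison == "low_vs_high"))
  expect_true(all(res$measure == "intensity"))
})

test_that("coefficient of variation uses sample sd and drops small groups", {
  tab <- data.frame(session_id = "S1", seal_id = "A",
                    condition = rep(c("low", "high"), c(3, 2)),
                    v = c(90, 100, 110, 5, 6))
  expect_message(cv <- coefficient_of_variation(tab, "v"), "dropped")
  expect_equal(nrow(cv), 1L)
  expect_equal(cv$cv, sd(c(90, 100, 110)) / 100)   # = 10 / 100
  tab2 <- data.frame(session_id = "S1", seal_id = "A", condition = "low",
                     v = c(100, 100, 100))
  expect_equal(coefficient_of_variation(tab2, "v")$cv, 0)
})

test_that("lower high-noise f0 dispersion is recovered by the CV analysis", {
  set.seed(64)
  rows <- list()
  for (s in 1:14) {
    des <- make_session_design(seed = 6400 + s)
    seals <- LETTERS[((s - 1) %/% 7) * 2 + 1:2]
    for (b in 1:9) {
      cond <- des$condition[b]
      cvt <- if (cond == "high") 0.05 else 0.08
      for (seal in seals) {
        n <- rpois(1, 3)
        if (n == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          session_id = sprintf("S%02d", s), seal_id = seal, condition = cond,
          trial_index = b, f0 = rlnorm(n, log(380), sqrt(log(1 + cvt^2))),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  suppressMessages(res <- cv_condition_analysis(tab, "f0", n_perm = 199, seed = 5))
  expect_true(all(res$cv_table$n >= 3))
  high_mean <- mean(res$cv_table$cv[res$cv_table$condition == "high"])
  other_mean <- mean(res$cv_table$cv[res$cv_table$condition != "high"])
  expect_lt(high_mean, other_mean)
  expect_true(res$main$significant)
})

test_that("call-rate tables include silent cells as zero counts", {
  ann <- data.frame(session_id = c("S1", "S1", "S1"),
                    seal_id = c("A", "A", "B"),
                    condition = c("low", "low", "high"))
  tab <- calls_per_group(ann)
  expect_equal(nrow(tab), 6L)                 # 1 session x 2 seals x 3 conditions
  expect_equal(sum(tab$n_calls), 3L)
  expect_equal(tab$n_calls[tab$seal_id == "A" & tab$condition == "low"], 2L)
  expect_equal(tab$n_calls[tab$seal_id == "B" & tab$condition == "low"], 0L)
})

test_that("result rows render as readable sentences", {
  res <- data.frame(comparison = "main", response = "f0_median_hz",
                    statistic = 12.3, p_perm = 0.000999, pseudo_r2 = 0.202,
                    n = 2576L, alpha_adjusted = 0.05, significant = TRUE)
  line <- render_results_text(res)
  expect_match(line, "pseudoR2 = 0.202")
  expect_match(line, "p < 0.001")
  expect_match(line, "N = 2576")
})
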