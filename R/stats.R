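#' Fit a random-intercept model for a response against noise condition
#'
#' Restricted-likelihood linear mixed model with random intercepts for
#' session and seal and fixed effects for condition (and trial index, when
#' the table has one): the inference backbone for call rate, duration, f0
#' and the coefficient-of-variation analyses. Pseudo-R^2 is the squared
#' correlation between fitted and observed response (fitted values include
#' the predicted random intercepts). The likelihood-ratio statistic against
#' the condition-free null model is computed from maximum-likelihood refits.
#'
#' Random factors with fewer than two levels are dropped with a message;
#' a singular fit triggers a refit without the zero-variance components.
#' With no usable random factor the model degrades to ordinary least
#' squares, whose fixed estimates are the zero-variance limit.
#'
#' @param table data.frame with the response, `condition`, and the random
#'   factor columns.
#' @param response Name of the response column.
#' @param fixed Fixed-effect terms; `condition` is treated as a factor,
#'   other terms as given. Terms missing from the table are dropped.
#' @param random Random-intercept factor columns.
#' @return List: `model` (lmer or lm fit), `pseudo_r2`, `lr_stat` (LR of the
#'   condition effect), `n`, `fixef`, `varcomp` (named variances incl.
#'   residual), `dropped` (random terms removed).
#' @export
fit_random_intercept_model <- function(table, response,
                                       fixed = c("condition", "trial_index"),
                                       random = c("session_id", "seal_id")) {
  stopifnot(response %in% names(table))
  y <- table[[response]]
  if (anyNA(y)) stop("missing values in response '", response, "'")
  tab <- table
  tab$condition <- factor(tab$condition, levels = CONDITIONS)
  tab$condition <- droplevels(tab$condition)
  fixed <- fixed[fixed %in% names(tab)]
  fixed <- fixed[vapply(fixed, function(f) length(unique(tab[[f]])) > 1, logical(1))]
  random <- random[random %in% names(tab)]

  dropped <- character(0)
  usable <- vapply(random, function(r) length(unique(tab[[r]])) >= 2, logical(1))
  dropped <- c(dropped, random[!usable])
  random <- random[usable]
  if (length(dropped)) message("dropping random terms with < 2 levels: ",
                               paste(dropped, collapse = ", "))

  fe <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  fit_once <- function(rand, reml = TRUE) {
    if (length(rand) == 0) {
      stats::lm(stats::reformulate(fe, response = response), data = tab)
    } else {
      re <- paste(sprintf("(1 | %s)", rand), collapse = " + ")
      lme4::lmer(stats::as.formula(paste(response, "~", fe, "+", re)),
                 data = tab, REML = reml)
    }
  }
  fit <- fit_once(random)
  if (length(random) && lme4::isSingular(fit, tol = 1e-5)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    zero <- vc$grp[vc$grp != "Residual" & vc$vcov < 1e-8 * stats::var(y)]
    if (length(zero)) {
      message("singular fit; dropping zero-variance random terms: ",
              paste(zero, collapse = ", "))
      dropped <- c(dropped, zero)
      random <- setdiff(random, zero)
      fit <- fit_once(random)
    }
  }

  fitted_y <- stats::fitted(fit)
  pseudo_r2 <- if (stats::var(fitted_y) > 0 && stats::var(y) > 0)
    stats::cor(fitted_y, y)^2 else 0

  lr_stat <- NA_real_
  if ("condition" %in% fixed) {
    fe0 <- setdiff(fixed, "condition")
    fe0 <- if (length(fe0)) paste(fe0, collapse = " + ") else "1"
    if (length(random)) {
      full_ml <- fit_once(random, reml = FALSE)
      re <- paste(sprintf("(1 | %s)", random), collapse = " + ")
      null_ml <- lme4::lmer(stats::as.formula(paste(response, "~", fe0, "+", re)),
                            data = tab, REML = FALSE)
      lr_stat <- as.numeric(2 * (stats::logLik(full_ml) - stats::logLik(null_ml)))
    } else {
      null_lm <- stats::lm(stats::reformulate(fe0, response = response), data = tab)
      lr_stat <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(null_lm)))
    }
  }

  vc <- if (length(random)) {
    v <- as.data.frame(lme4::VarCorr(fit))
    stats::setNames(v$vcov, ifelse(v$grp == "Residual", "residual", v$grp))
  } else c(residual = stats::sigma(fit)^2)

  list(model = fit, pseudo_r2 = pseudo_r2, lr_stat = lr_stat,
       n = nrow(tab),
       fixef = if (length(random)) lme4::fixef(fit) else stats::coef(fit),
       varcomp = vc, dropped = dropped)
}

# --- fast GLS machinery for the permutation statistic -----------------------
#
# Variance components are estimated once under the condition-free null model;
# per permutation only the condition design columns change and the Wald
# chi-square for condition is evaluated by the Woodbury identity:
#   V = s2e I + Z D Z'  =>  A' V^-1 B  propto  A'B - (A'Z) M (Z'B),
# with M = (s2e D^-1 + Z'Z)^-1 a small q x q matrix. The residual-variance
# scale factor is constant across permutations and cancels from the p-value.
prep_gls <- function(table, response, fixed_other, random) {
  y <- table[[response]]
  fixed_other <- fixed_other[fixed_other %in% names(table)]
  fixed_other <- fixed_other[vapply(fixed_other, function(f)
    length(unique(table[[f]])) > 1, logical(1))]
  random <- random[random %in% names(table)]
  random <- random[vapply(random, function(r) length(unique(table[[r]])) >= 2, logical(1))]

  fe0 <- if (length(fixed_other)) paste(fixed_other, collapse = " + ") else "1"
  if (length(random)) {
    re <- paste(sprintf("(1 | %s)", random), collapse = " + ")
    fit0 <- lme4::lmer(stats::as.formula(paste(response, "~", fe0, "+", re)),
                       data = table, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit0))
    s2e <- vc$vcov[vc$grp == "Residual"]
    keep <- vc$grp[vc$grp != "Residual" & vc$vcov > 1e-10 * max(stats::var(y), 1e-300)]
    vars <- vc$vcov[match(keep, vc$grp)]
  } else {
    s2e <- stats::var(y)
    keep <- character(0); vars <- numeric(0)
  }

  if (length(keep)) {
    Zs <- lapply(keep, function(g) {
      f <- factor(table[[g]])
      stats::model.matrix(~ 0 + f)
    })
    Z <- do.call(cbind, Zs)
    d <- rep(vars, vapply(Zs, ncol, integer(1)))
    M <- solve(diag(s2e / d, nrow = length(d)) + crossprod(Z))
  } else {
    Z <- NULL; M <- NULL
  }
  X0 <- stats::model.matrix(stats::as.formula(paste("~", fe0)), data = table)
  list(y = y, X0 = X0, Z = Z, M = M)
}

gls_wald_stat <- function(prep, Xc) {
  X <- cbind(prep$X0, Xc)
  y <- prep$y
  if (is.null(prep$Z)) {
    XtX <- crossprod(X); Xty <- crossprod(X, y)
  } else {
    ZtX <- crossprod(prep$Z, X); Zty <- crossprod(prep$Z, y)
    XtX <- crossprod(X) - t(ZtX) %*% prep$M %*% ZtX
    Xty <- crossprod(X, y) - t(ZtX) %*% prep$M %*% Zty
  }
  S <- tryCatch(solve(XtX), error = function(e) MASS_ginv(XtX))
  beta <- S %*% Xty
  ic <- (ncol(prep$X0) + 1L):ncol(X)
  bc <- beta[ic, , drop = FALSE]
  Scc <- S[ic, ic, drop = FALSE]
  as.numeric(t(bc) %*% solve(Scc, bc))
}

# tiny pseudo-inverse fallback; avoids importing MASS for a corner case
MASS_ginv <- function(A, tol = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  pos <- e$values > tol * max(e$values)
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

# Permute condition labels respecting the exchangeability unit. Conditions
# were randomized at the session level (one block order, heard by both housed
# seals), so: tables with `trial_index` (block ids) get their block-level
# condition map permuted within session, carrying all of a block's calls
# along; per-group tables (one row per session x seal x condition) get a
# condition relabelling drawn per session and applied to every seal in it.
permute_conditions <- function(table) {
  cond <- table$condition
  if ("trial_index" %in% names(table) &&
      any(duplicated(paste(table$session_id, table$trial_index)))) {
    for (s in unique(table$session_id)) {
      rows <- which(table$session_id == s)
      blk <- table$trial_index[rows]
      ublk <- unique(blk)
      bc <- cond[rows][match(ublk, blk)]
      cond[rows] <- sample(bc)[match(blk, ublk)]
    }
  } else {
    for (s in unique(table$session_id)) {
      rows <- which(table$session_id == s)
      present <- unique(cond[rows])
      relabel <- stats::setNames(sample(present), present)
      cond[rows] <- unname(relabel[cond[rows]])
    }
  }
  cond
}

#' Permutation p-value for the condition effect
#'
#' Monte Carlo permutation test: condition labels are permuted within session
#' (at the block level when the table carries block ids, preserving the
#' within-block dependence of calls), the test statistic is recomputed, and
#' `p = (1 + #{perm >= observed}) / (1 + n_perm)`.
#'
#' Two statistics are available. The default `"gls_wald"` is the likelihood
#' -ratio-equivalent Wald chi-square for condition under generalized least
#' squares with variance components estimated once from the condition-free
#' null model — label-symmetric, hence a valid permutation statistic, and
#' fast enough for calibration studies. `"full_lr"` refits the mixed model by
#' maximum likelihood for every permutation and uses the likelihood ratio
#' against the condition-free model.
#'
#' @param table data.frame with `condition`, random factor columns, and the
#'   response.
#' @param response Response column name.
#' @param fixed_other Fixed-effect terms besides condition (kept in both
#'   null and full models).
#' @param random Random-intercept factors.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param statistic `"gls_wald"` (default) or `"full_lr"`.
#' @return List: `p_perm`, `stat_obs`, `n_perm`, `statistic`.
#' @export
permutation_p <- function(table, response, fixed_other = "trial_index",
                          random = c("session_id", "seal_id"),
                          n_perm = 1000L, seed = 1L,
                          statistic = c("gls_wald", "full_lr")) {
  statistic <- match.arg(statistic)
  stopifnot(n_perm >= 1L)
  tab <- table
  tab$condition <- droplevels(factor(tab$condition, levels = CONDITIONS))
  if (nlevels(tab$condition) < 2)
    return(list(p_perm = NA_real_, stat_obs = NA_real_, n_perm = n_perm,
                statistic = statistic,
                note = "fewer than 2 conditions present"))

  if (statistic == "gls_wald") {
    prep <- prep_gls(tab, response, fixed_other, random)
    stat_fun <- function(cond) {
      Xc <- stats::model.matrix(~ cond)[, -1, drop = FALSE]
      gls_wald_stat(prep, Xc)
    }
  } else {
    fe0 <- fixed_other[fixed_other %in% names(tab)]
    stat_fun <- function(cond) {
      t2 <- tab; t2$condition <- cond
      fit_random_intercept_model(t2, response,
                                 fixed = c("condition", fe0),
                                 random = random)$lr_stat
    }
  }

  obs <- stat_fun(tab$condition)
  exceed <- 0L
  rng_local(derive_seed(seed, 37L), {
    for (b in seq_len(n_perm)) {
      cond_b <- factor(permute_conditions(tab), levels = levels(tab$condition))
      if (stat_fun(cond_b) >= obs) exceed <- exceed + 1L
    }
  })
  list(p_perm = (1 + exceed) / (1 + n_perm), stat_obs = obs,
       n_perm = n_perm, statistic = statistic)
}

#' Permutation-tested condition effect, packaged as a result row
#'
#' @inheritParams permutation_p
#' @param alpha_adjusted Significance threshold after multiplicity
#'   adjustment.
#' @param label Comparison label for the results table.
#' @param fixed Fixed terms for the descriptive mixed-model fit (the
#'   permutation always controls for `fixed_other`).
#' @return One-row data.frame: `comparison`, `response`, `statistic`,
#'   `p_perm`, `pseudo_r2`, `n`, `alpha_adjusted`, `significant`.
#' @export
condition_effect_test <- function(table, response, fixed_other = "trial_index",
                                  random = c("session_id", "seal_id"),
                                  n_perm = 1000L, seed = 1L,
                                  alpha_adjusted = 0.05, label = "main",
                                  statistic = "gls_wald") {
  fit <- fit_random_intercept_model(table, response,
                                    fixed = c("condition", fixed_other),
                                    random = random)
  pp <- permutation_p(table, response, fixed_other, random, n_perm, seed,
                      statistic = statistic)
  data.frame(comparison = label, response = response,
             statistic = pp$stat_obs, p_perm = pp$p_perm,
             pseudo_r2 = fit$pseudo_r2, n = fit$n,
             alpha_adjusted = alpha_adjusted,
             significant = !is.na(pp$p_perm) && pp$p_perm < alpha_adjusted,
             stringsAsFactors = FALSE)
}

#' Pairwise condition comparisons with Bonferroni control
#'
#' Refits the permutation-tested model on each two-condition subset; the
#' three pairwise comparisons use the Bonferroni-adjusted threshold
#' `0.05 / 3` (about 0.0167).
#'
#' @inheritParams condition_effect_test
#' @return data.frame with one row per condition pair.
#' @export
pairwise_condition_tests <- function(table, response, fixed_other = "trial_index",
                                     random = c("session_id", "seal_id"),
                                     n_perm = 1000L, seed = 1L,
                                     statistic = "gls_wald") {
  pairs <- list(c("no_playback", "low"), c("no_playback", "high"), c("low", "high"))
  out <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    sub <- table[table$condition %in% pr, , drop = FALSE]
    condition_effect_test(sub, response, fixed_other, random, n_perm,
                          seed = derive_seed(seed, 41L, i),
                          alpha_adjusted = 0.05 / 3,
                          label = paste(pr, collapse = "_vs_"),
                          statistic = statistic)
  })
  do.call(rbind, out)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test: the exact U distribution when the smaller sample
#' has at most 12 observations and there are no ties, otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return List: `U` (statistic for `x`), `p` (two-sided).
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= 12
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Bonferroni-adjusted significance thresholds
#'
#' `bonferroni_alpha_pairwise()` is the threshold for the three pairwise
#' condition comparisons (0.05 / 3). `bonferroni_alpha_per_seal()` is the
#' threshold for the per-seal Mann-Whitney family: `n_seals` individuals
#' times three condition pairs (0.05 / 24 in the eight-seal design).
#'
#' @param alpha Family-wise error level.
#' @param n_seals Number of individuals in the per-seal family.
#' @return Adjusted threshold.
#' @export
bonferroni_alpha_pairwise <- function(alpha = 0.05) alpha / 3

#' @rdname bonferroni_alpha_pairwise
#' @export
bonferroni_alpha_per_seal <- function(n_seals = 8, alpha = 0.05) alpha / (3 * n_seals)

#' Per-seal Mann-Whitney tests of intensity and spectral tilt
#'
#' Intensity and the two tilt measures are strongly non-normal, so each seal
#' is tested separately with Mann-Whitney U tests across the three condition
#' pairs, at the Bonferroni threshold `0.05 / (3 * n_seals)`. Comparisons
#' with an empty condition cell are skipped with a message. NA measure
#' values (discarded tilt estimates) are dropped per comparison.
#'
#' @param features Per-call feature table (use the clean subset for these
#'   measures).
#' @param measures Named character: result label -> feature column.
#' @param alpha Family-wise error level.
#' @return data.frame: `seal_id`, `measure`, `comparison`, `U`, `p`, `n_x`,
#'   `n_y`, `alpha_adjusted`, `significant`.
#' @export
per_seal_intensity_tests <- function(
    features,
    measures = c(intensity = "intensity_linear",
                 octave_slope = "octave_slope_db_per_oct",
                 r14 = "r14_db"),
    alpha = 0.05) {
  seals <- sort(unique(features$seal_id))
  alpha_adj <- bonferroni_alpha_per_seal(length(seals), alpha)
  pairs <- list(c("no_playback", "low"), c("no_playback", "high"), c("low", "high"))
  rows <- list()
  for (seal in seals) for (m in names(measures)) for (pr in pairs) {
    col <- measures[[m]]
    x <- features[features$seal_id == seal & features$condition == pr[1], col]
    y <- features[features$seal_id == seal & features$condition == pr[2], col]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0) {
      message(sprintf("skipping %s / %s / %s: empty condition cell",
                      seal, m, paste(pr, collapse = " vs ")))
      next
    }
    mw <- mann_whitney(x, y)
    rows[[length(rows) + 1L]] <- data.frame(
      seal_id = seal, measure = m, comparison = paste(pr, collapse = "_vs_"),
      U = mw$U, p = mw$p, n_x = length(x), n_y = length(y),
      alpha_adjusted = alpha_adj, significant = mw$p < alpha_adj,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seal_id = character(), measure = character(),
               comparison = character(), U = numeric(), p = numeric(),
               n_x = integer(), n_y = integer(), alpha_adjusted = numeric(),
               significant = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Coefficient of variation per session, seal and condition
#'
#' Dispersion analysis: CV = sample sd (n - 1 denominator) over mean within
#' each (session, seal, condition) group; groups with fewer than
#' `min_group_size` calls are dropped with a message.
#'
#' @param table Call-level table with the response column.
#' @param response Response column (`duration_s` or `f0_median_hz`).
#' @param min_group_size Minimum calls per group.
#' @return data.frame: `session_id`, `seal_id`, `condition`, `n`, `mean`,
#'   `sd`, `cv`.
#' @export
coefficient_of_variation <- function(table, response, min_group_size = 3L) {
  stopifnot(response %in% names(table))
  tab <- table[!is.na(table[[response]]), , drop = FALSE]
  key <- interaction(tab$session_id, tab$seal_id, tab$condition, drop = TRUE)
  agg <- do.call(rbind, lapply(split(tab, key), function(g) {
    data.frame(session_id = g$session_id[1], seal_id = g$seal_id[1],
               condition = g$condition[1], n = nrow(g),
               mean = mean(g[[response]]), sd = stats::sd(g[[response]]),
               stringsAsFactors = FALSE)
  }))
  small <- agg$n < min_group_size
  if (any(small))
    message(sum(small), " group(s) with fewer than ", min_group_size,
            " calls dropped from CV analysis")
  agg <- agg[!small, , drop = FALSE]
  agg$cv <- agg$sd / agg$mean
  rownames(agg) <- NULL
  agg
}

#' Condition effect on the coefficient of variation
#'
#' Groups the response into per-(session, seal, condition) CVs and runs the
#' permutation-tested random-intercept model (main effect plus the three
#' pairwise comparisons) on the CV table. Trial index does not exist at the
#' group level, so condition is the only fixed effect.
#'
#' @inheritParams coefficient_of_variation
#' @inheritParams condition_effect_test
#' @return List: `cv_table`, `main` (one-row result), `pairwise` (three
#'   rows).
#' @export
cv_condition_analysis <- function(table, response, min_group_size = 3L,
                                  n_perm = 1000L, seed = 1L,
                                  statistic = "gls_wald") {
  cv_tab <- coefficient_of_variation(table, response, min_group_size)
  if (nrow(cv_tab) < 6 || length(unique(cv_tab$condition)) < 2) {
    return(list(cv_table = cv_tab, main = NULL, pairwise = NULL,
                note = "insufficient data for CV analysis"))
  }
  main <- condition_effect_test(cv_tab, "cv", fixed_other = character(0),
                                random = c("session_id", "seal_id"),
                                n_perm = n_perm, seed = seed,
                                label = "main", statistic = statistic)
  main$response <- paste0("cv_", response)
  pw <- pairwise_condition_tests(cv_tab, "cv", fixed_other = character(0),
                                 random = c("session_id", "seal_id"),
                                 n_perm = n_perm, seed = seed,
                                 statistic = statistic)
  pw$response <- paste0("cv_", response)
  list(cv_table = cv_tab, main = main, pairwise = pw)
}

#' Calls per session, seal and condition
#'
#' Builds the call-rate table: one row per (session, seal, condition) cell of
#' the full design grid, with `n_calls = 0` for cells where a seal stayed
#' silent, so silence is informative rather than missing.
#'
#' @param annotations Annotation (or feature) table with `session_id`,
#'   `seal_id`, `condition`.
#' @return data.frame: `session_id`, `seal_id`, `condition`, `n_calls`.
#' @export
calls_per_group <- function(annotations) {
  grid <- expand.grid(
    condition = CONDITIONS,
    seal_id = sort(unique(annotations$seal_id)),
    session_id = sort(unique(annotations$session_id)),
    stringsAsFactors = FALSE)[, c("session_id", "seal_id", "condition")]
  key_g <- paste(grid$session_id, grid$seal_id, grid$condition)
  key_a <- paste(annotations$session_id, annotations$seal_id, annotations$condition)
  grid$n_calls <- as.integer(table(factor(key_a, levels = key_g)))
  grid
}

#' Render a results table in sentence form
#'
#' One line per row of a results table, in the style
#' `response [comparison]: pseudoR2 = 0.202; p < 0.001; N = 2576 (*)`.
#'
#' @param results data.frame from [condition_effect_test()] /
#'   [pairwise_condition_tests()].
#' @return Character vector of lines.
#' @export
render_results_text <- function(results) {
  vapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    pstr <- if (is.na(r$p_perm)) "p = NA"
            else if (r$p_perm < 0.001) "p < 0.001"
            else sprintf("p = %.3f", r$p_perm)
    sprintf("%s [%s]: pseudoR2 = %.3f; %s; N = %d%s",
            r$response, r$comparison, r$pseudo_r2, pstr, r$n,
            if (isTRUE(r$significant)) " (*)" else "")
  }, character(1))
}
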