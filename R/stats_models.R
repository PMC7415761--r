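# Inferential layer: t tests with Cohen's d and noncentral-t confidence
# intervals, binomial-logit GLMMs for success, Gaussian LMMs for effort with
# Satterthwaite denominator degrees of freedom, AIC model selection with
# likelihood-ratio tests, and the showing-accuracy vs time correlation.
#
# All mixed models carry a single random intercept per dog-owner pair, the
# repeated unit of the design. Estimation is by lme4 (Laplace approximation
# for the GLMM); on a convergence warning the model is refit with the BOBYQA
# optimizer. Rows with missing values on any model variable are excluded
# listwise per model. Everything is two-sided at alpha = 0.05.

# ---- t tests and effect sizes ----------------------------------------------

# Confidence interval for a standardized mean difference via inversion of the
# noncentral t distribution: the ncp bounds solve pt(t, df, ncp) = (1+c)/2
# and (1-c)/2, and d = ncp / sqrt(n).
.ncp_ci <- function(t, df, conf = 0.95) {
  alpha <- (1 - conf) / 2
  span <- max(20, 2 * abs(t) + 20)
  solve_one <- function(p) {
    # pnt warns about tail precision far from the root; harmless here
    f <- function(ncp) suppressWarnings(pt(t, df, ncp)) - p
    lo <- t - span; hi <- t + span
    while (f(lo) < 0) lo <- lo - span
    while (f(hi) > 0) hi <- hi + span
    uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  c(solve_one(1 - alpha), solve_one(alpha))
}

.test_result <- function(statistic, df, p, d, d_ci, extra = list()) {
  structure(c(list(statistic = statistic, df = df, p = p,
                   d = d, d_ci = d_ci), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("t(%s) = %.3f, p = %.4g, Cohen's d = %.3f [%.3f, %.3f]\n",
              format(x$df), x$statistic, x$p, x$d, x$d_ci[1], x$d_ci[2]))
  invisible(x)
}

#' One-sample t test against a chance level
#'
#' Tests per-pair success percentages against the chance level of the task
#' (25% for a four-box choice). Cohen's d is the mean deviation from chance
#' divided by the sample SD, with its confidence interval from noncentral-t
#' inversion.
#'
#' @param x Numeric vector, one value per pair (at least 2).
#' @param chance Null value, on the same scale as `x` (default 25, percent).
#' @param conf Confidence level for the d interval.
#' @return A `test_result`: `statistic`, `df`, `p` (two-sided), `d`, `d_ci`,
#'   plus `mean`, `sd`, `n`, `chance`.
#' @export
one_sample_t_vs_chance <- function(x, chance = 25, conf = 0.95) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  s <- sd(x)
  if (s == 0) stop("zero variance: all values identical", call. = FALSE)
  m <- mean(x)
  t <- (m - chance) / (s / sqrt(n))
  df <- n - 1
  p <- 2 * pt(-abs(t), df)
  d <- (m - chance) / s
  d_ci <- .ncp_ci(t, df, conf) / sqrt(n)
  .test_result(t, df, p, d, d_ci,
               list(mean = m, sd = s, n = n, chance = chance))
}

#' Paired t test with Cohen's d
#'
#' Two-sided paired t test on `a - b`. The effect size is reported both as
#' mean difference over the SD of the differences (`d`, the default) and
#' over the pooled SD of the two samples (`d_pooled`); `d_method` selects
#' which one carries the confidence interval.
#'
#' @param a,b Numeric vectors of equal length (>= 2), matched element-wise.
#' @param d_method `"diff"` or `"pooled"`.
#' @param conf Confidence level.
#' @return A `test_result` with both d variants and the input means/SDs.
#' @export
paired_t <- function(a, b, d_method = c("diff", "pooled"), conf = 0.95) {
  d_method <- match.arg(d_method)
  if (length(a) != length(b)) stop("unequal lengths", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  dif <- a - b
  sdd <- sd(dif)
  if (sdd == 0) stop("zero variance of differences", call. = FALSE)
  t <- mean(dif) / (sdd / sqrt(n))
  df <- n - 1
  p <- 2 * pt(-abs(t), df)
  d_diff <- mean(dif) / sdd
  sp <- sqrt((var(a) + var(b)) / 2)
  d_pooled <- if (sp > 0) mean(dif) / sp else NA_real_
  ci_diff <- .ncp_ci(t, df, conf) / sqrt(n)
  if (d_method == "diff") {
    d <- d_diff; d_ci <- ci_diff
  } else {
    d <- d_pooled
    d_ci <- ci_diff * (sdd / sp)  # rescaled diff-based interval
  }
  .test_result(t, df, p, d, d_ci,
               list(d_diff = d_diff, d_pooled = d_pooled,
                    mean_a = mean(a), sd_a = sd(a),
                    mean_b = mean(b), sd_b = sd(b), n = n))
}

# ---- nested time coding ----------------------------------------------------

#' Add the nested time covariates to an observation table
#'
#' The temporal design is nested: phases within trials within sessions.
#' Following the reported contrasts ("effect of trial in session 1", "phase
#' in session 1 and 2"), time enters models as a session main effect plus a
#' centered linear trial term within each session plus a phase-2 dummy
#' within each session.
#'
#' @param obs Observation table.
#' @return `obs` with added numeric columns `session2`, `trial_s1`,
#'   `trial_s2`, `phase_s1`, `phase_s2`.
#' @export
add_time_covariates <- function(obs) {
  s1 <- obs$session == 1
  obs$session2 <- as.numeric(!s1)
  obs$trial_s1 <- ifelse(s1, obs$trial - 2.5, 0)
  obs$trial_s2 <- ifelse(!s1, obs$trial - 2.5, 0)
  obs$phase_s1 <- as.numeric(s1 & obs$phase == 2)
  obs$phase_s2 <- as.numeric(!s1 & obs$phase == 2)
  obs
}

#' @rdname add_time_covariates
#' @export
time_terms <- function() {
  c("session2", "trial_s1", "trial_s2", "phase_s1", "phase_s2")
}

# ---- mixed models ----------------------------------------------------------

.drop_incomplete <- function(rows, vars) {
  keep <- stats::complete.cases(rows[, vars, drop = FALSE])
  list(rows = rows[keep, , drop = FALSE], n_excluded = sum(!keep))
}

.check_design <- function(rows, fixed) {
  mm <- model.matrix(fixed, rows)
  if (qr(mm)$rank < ncol(mm)) {
    stop("singular fixed-effect design (constant or collinear predictor)",
         call. = FALSE)
  }
  invisible(mm)
}

# Fit, watching for lme4 convergence warnings; on one, refit with BOBYQA.
# A boundary ("singular") fit is not a convergence failure: a random-intercept
# variance estimated as 0 is a legitimate optimum.
.lme4_problems <- function(m, warn_messages) {
  msgs <- c(warn_messages, unlist(m@optinfo$conv$lme4$messages))
  msgs <- msgs[!grepl("boundary \\(singular\\)|isSingular", msgs)]
  any(grepl("converge|Hessian", msgs, ignore.case = TRUE))
}

.fit_with_fallback <- function(fit_fun, make_control) {
  fit_once <- function(ctrl) {
    messages <- character()
    m <- withCallingHandlers(
      fit_fun(ctrl),
      warning = function(w) {
        messages <<- c(messages, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(c) {
        messages <<- c(messages, conditionMessage(c))
        invokeRestart("muffleMessage")
      })
    list(model = m, bad = .lme4_problems(m, messages))
  }
  res <- fit_once(make_control(NULL))
  optimizer <- "default"
  if (res$bad) {
    res <- fit_once(make_control("bobyqa"))
    optimizer <- "bobyqa"
  }
  list(model = res$model, converged = !res$bad, optimizer = optimizer)
}

.coef_table <- function(m, wald_z = TRUE, satt_df = NULL) {
  sm <- summary(m)$coefficients
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  stat <- est / se
  if (wald_z) {
    data.frame(term = rownames(sm), estimate = est, se = se, z = stat,
               p = 2 * pnorm(-abs(stat)), row.names = NULL,
               stringsAsFactors = FALSE)
  } else {
    df <- if (is.null(satt_df)) rep(NA_real_, length(est)) else satt_df
    data.frame(term = rownames(sm), estimate = est, se = se, t = stat,
               df = df, p = 2 * pt(-abs(stat), df), row.names = NULL,
               stringsAsFactors = FALSE)
  }
}

.make_fit <- function(model, family, coefs, fitted_info) {
  ll <- logLik(model)
  structure(list(
    family = family,
    coefficients = coefs,
    random = list(pair_intercept_var = as.numeric(lme4::VarCorr(model)[[1]]),
                  residual_sd = stats::sigma(model)),
    logLik = as.numeric(ll),
    k = attr(ll, "df"),
    AIC = as.numeric(AIC(model)),
    nobs = stats::nobs(model),
    n_excluded = fitted_info$n_excluded,
    converged = fitted_info$converged,
    optimizer = fitted_info$optimizer,
    formula = fitted_info$formula,
    REML = isTRUE(fitted_info$REML),
    model = model
  ), class = "canishow_fit")
}

#' @export
print.canishow_fit <- function(x, ...) {
  cat(sprintf("<%s mixed model> %s\n", x$family, deparse(x$formula)))
  cat(sprintf("  n = %d (%d rows excluded), logLik = %.2f, AIC = %.2f%s\n",
              x$nobs, x$n_excluded, x$logLik, x$AIC,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Binomial-logit mixed model for communication success
#'
#' Fits a generalized linear mixed model with binomial family and logit
#' link: the response is whether the pair chose the target box, with a
#' random intercept per pair and the fixed effects given in `fixed`
#' (typically the correct-showing proportion, condition, and the nested time
#' terms; see [add_time_covariates()]). Estimated by Laplace-approximate ML;
#' Wald z statistics. Rows missing any model variable are dropped first.
#'
#' @param rows Observation table with a logical/0-1 `success` column and a
#'   `pair` column.
#' @param fixed One-sided fixed-effects formula such as
#'   `success ~ prop_correct_showing + session2`.
#' @return A `canishow_fit`: coefficient table (estimate, SE, z, p), random
#'   intercept variance, logLik, AIC, convergence flag and the optimizer
#'   used.
#' @export
fit_success_glmm <- function(rows, fixed = success ~ prop_correct_showing) {
  vars <- c(all.vars(fixed), "pair")
  cc <- .drop_incomplete(rows, vars)
  dat <- cc$rows
  if (!nrow(dat)) stop("no complete rows for model variables", call. = FALSE)
  dat$success <- as.numeric(dat$success)
  .check_design(dat, fixed)
  full <- update(fixed, . ~ . + (1 | pair))
  res <- .fit_with_fallback(
    function(ctrl) lme4::glmer(full, data = dat, family = stats::binomial(),
                               control = ctrl),
    function(opt) {
      if (is.null(opt)) lme4::glmerControl(calc.derivs = TRUE)
      else lme4::glmerControl(optimizer = opt)
    }
  )
  .make_fit(res$model, "binomial-logit",
            .coef_table(res$model, wald_z = TRUE),
            list(n_excluded = cc$n_excluded, converged = res$converged,
                 optimizer = res$optimizer, formula = full, REML = FALSE))
}

#' Gaussian mixed model for showing effort
#'
#' Fits a linear mixed model with a random intercept per pair, by REML by
#' default. t statistics use Satterthwaite denominator degrees of freedom
#' computed for the random-intercept model class (see
#' [satterthwaite_df()]).
#'
#' @param rows Observation table; rows with undefined effort (no low- or
#'   high-effort showings) are excluded listwise with any other missing
#'   model variable.
#' @param fixed Fixed-effects formula, e.g. `effort ~ phase_s1 + phase_s2`.
#' @param REML Use REML (default) or ML (needed when the fit enters a
#'   likelihood-ratio comparison of fixed effects).
#' @return A `canishow_fit` with a t/df/p coefficient table.
#' @export
fit_effort_lmm <- function(rows, fixed = effort ~ phase_s1 + phase_s2,
                           REML = TRUE) {
  vars <- c(all.vars(fixed), "pair")
  cc <- .drop_incomplete(rows, vars)
  dat <- cc$rows
  if (!nrow(dat)) stop("no complete rows for model variables", call. = FALSE)
  resp <- all.vars(fixed)[1L]
  if (sd(dat[[resp]]) == 0) {
    stop("zero-variance response", call. = FALSE)
  }
  .check_design(dat, fixed)
  full <- update(fixed, . ~ . + (1 | pair))
  res <- .fit_with_fallback(
    function(ctrl) lme4::lmer(full, data = dat, REML = REML, control = ctrl),
    function(opt) {
      if (is.null(opt)) lme4::lmerControl()
      else lme4::lmerControl(optimizer = opt)
    }
  )
  dfs <- tryCatch(satterthwaite_df(res$model), error = function(e) NULL)
  .make_fit(res$model, "gaussian",
            .coef_table(res$model, wald_z = FALSE, satt_df = dfs),
            list(n_excluded = cc$n_excluded, converged = res$converged,
                 optimizer = res$optimizer, formula = full, REML = REML))
}

# ---- Satterthwaite degrees of freedom --------------------------------------

# -2 log (restricted) likelihood and vcov(beta) of the Gaussian
# random-intercept model at variance parameters (tau2, sig2), by block
# algebra: for group j with n_j rows, V_j = sig2 I + tau2 J, so
# V_j^{-1} = I/sig2 - tau2/(sig2 (sig2 + n_j tau2)) J and
# log|V_j| = (n_j - 1) log sig2 + log(sig2 + n_j tau2).
.ri_crit <- function(y, X, groups, tau2, sig2, reml = TRUE) {
  p <- ncol(X)
  XtViX <- matrix(0, p, p)
  XtViy <- numeric(p)
  ytViy <- 0
  ldV <- 0
  for (idx in groups) {
    nj <- length(idx)
    Xj <- X[idx, , drop = FALSE]
    yj <- y[idx]
    den <- sig2 + nj * tau2
    w <- tau2 / (sig2 * den)
    cs_X <- colSums(Xj)
    cs_y <- sum(yj)
    XtViX <- XtViX + crossprod(Xj) / sig2 - w * tcrossprod(cs_X)
    XtViy <- XtViy + crossprod(Xj, yj) / sig2 - w * cs_X * cs_y
    ytViy <- ytViy + sum(yj^2) / sig2 - w * cs_y^2
    ldV <- ldV + (nj - 1) * log(sig2) + log(den)
  }
  beta <- solve(XtViX, XtViy)
  rss <- as.numeric(ytViy - sum(beta * XtViy))
  m2l <- ldV + rss
  if (reml) m2l <- m2l + as.numeric(determinant(XtViX)$modulus)
  list(m2l = m2l, vb = solve(XtViX))
}

#' Satterthwaite degrees of freedom for a random-intercept lmer fit
#'
#' For each fixed coefficient b with sampling variance f(tau2, sig2) =
#' Var(b), the Satterthwaite approximation is df = 2 f^2 / (g' W g), where g
#' is the gradient of f in the two variance parameters (random-intercept and
#' residual variance) and W is the asymptotic covariance of their estimates,
#' obtained from the finite-difference Hessian of the (RE)ML criterion.
#' Implemented directly for the single-scalar-random-intercept model class
#' this package fits; models with other random-effect structures are
#' rejected. At a boundary estimate (random-intercept variance ~ 0) the
#' classical residual df n - p is returned.
#'
#' @param m A fitted `lmerMod` with exactly one random term, `(1 | group)`.
#' @return Numeric vector of df, one per fixed coefficient, clamped to
#'   `[1, n - p]`.
#' @export
satterthwaite_df <- function(m) {
  if (!inherits(m, "lmerMod")) stop("need an lmer fit", call. = FALSE)
  fl <- lme4::getME(m, "flist")
  cn <- lme4::getME(m, "cnms")
  if (length(fl) != 1L || length(cn) != 1L || !identical(cn[[1]], "(Intercept)")) {
    stop("satterthwaite_df supports a single random intercept only",
         call. = FALSE)
  }
  y <- lme4::getME(m, "y")
  X <- lme4::getME(m, "X")
  groups <- split(seq_along(y), fl[[1]])
  reml <- lme4::isREML(m)
  tau2 <- as.numeric(lme4::VarCorr(m)[[1]])
  sig2 <- stats::sigma(m)^2
  n <- length(y)
  p <- ncol(X)
  if (tau2 < 1e-8 * sig2) return(rep(n - p, p))
  f <- function(v) .ri_crit(y, X, groups, v[1], v[2], reml = reml)
  est <- c(tau2, sig2)
  h <- est * 1e-4
  # 9-point stencil: center, axial +/- h, corners
  ev <- list(
    c0 = f(est),
    p1 = f(est + c(h[1], 0)), m1 = f(est - c(h[1], 0)),
    p2 = f(est + c(0, h[2])), m2 = f(est - c(0, h[2])),
    pp = f(est + h), pm = f(est + c(h[1], -h[2])),
    mp = f(est + c(-h[1], h[2])), mm = f(est - h)
  )
  H <- matrix(0, 2, 2)
  H[1, 1] <- (ev$p1$m2l + ev$m1$m2l - 2 * ev$c0$m2l) / h[1]^2
  H[2, 2] <- (ev$p2$m2l + ev$m2$m2l - 2 * ev$c0$m2l) / h[2]^2
  H[1, 2] <- H[2, 1] <-
    (ev$pp$m2l - ev$pm$m2l - ev$mp$m2l + ev$mm$m2l) / (4 * h[1] * h[2])
  W <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(W)) return(rep(n - p, p))
  dfs <- vapply(seq_len(p), function(i) {
    fi <- ev$c0$vb[i, i]
    g <- c((ev$p1$vb[i, i] - ev$m1$vb[i, i]) / (2 * h[1]),
           (ev$p2$vb[i, i] - ev$m2$vb[i, i]) / (2 * h[2]))
    denom <- as.numeric(t(g) %*% W %*% g)
    if (denom <= 0) return(n - p)
    2 * fi^2 / denom
  }, numeric(1))
  pmin(pmax(dfs, 1), n - p)
}

# ---- model selection -------------------------------------------------------

#' AIC model selection with likelihood-ratio tests
#'
#' Selects the fit with the smallest AIC (ties broken by declaration order)
#' among candidate models fit to identical rows, and reports the chi-square
#' likelihood-ratio test for each declared nested pair: chi2 = 2 (logLik
#' larger - logLik smaller) on df = difference in parameter count.
#'
#' @param fits Named list of `canishow_fit` objects on the same rows.
#' @param nested Optional list of `c("smaller", "larger")` name pairs for
#'   which to report LRTs.
#' @return A `model_comparison`: AIC table (`model`, `k`, `logLik`, `AIC`,
#'   `delta_AIC`), `selected` (name), and the LRT table.
#' @export
select_model_aic <- function(fits, nested = NULL) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model_", seq_along(fits))
  }
  nobs <- vapply(fits, function(f) f$nobs, numeric(1))
  if (length(unique(nobs)) != 1L) {
    stop("fits use different row sets; AIC values are not comparable",
         call. = FALSE)
  }
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  ll <- vapply(fits, function(f) f$logLik, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  tab <- data.frame(model = names(fits), k = k, logLik = ll, AIC = aic,
                    delta_AIC = aic - min(aic), row.names = NULL,
                    stringsAsFactors = FALSE)
  sel <- names(fits)[which.min(aic)]  # which.min takes the first on ties
  lrt <- NULL
  if (!is.null(nested)) {
    lrt <- do.call(rbind, lapply(nested, function(pr) {
      s <- fits[[pr[1]]]; l <- fits[[pr[2]]]
      if (is.null(s) || is.null(l)) stop("unknown model name in `nested`",
                                         call. = FALSE)
      if (s$REML || l$REML) {
        warning("LRT on REML fits compares fixed effects unreliably; ",
                "refit with REML = FALSE")
      }
      chi2 <- 2 * (l$logLik - s$logLik)
      df <- l$k - s$k
      data.frame(smaller = pr[1], larger = pr[2], chisq = chi2, df = df,
                 p = pchisq(chi2, df, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(table = tab, selected = sel, lrt = lrt),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table, digits = 4)
  cat("selected:", x$selected, "\n")
  if (!is.null(x$lrt)) print(x$lrt, digits = 4)
  invisible(x)
}

# ---- accuracy vs time ------------------------------------------------------

#' Correlation between showing accuracy and seconds within a trial
#'
#' Pearson correlation between the per-showing 0/1 accuracy flag (referent
#' equals target) and the showing's anchor second within its trial (phase-2
#' anchors are offset by the phase-1 duration upstream). The t statistic has
#' n - 2 df; the confidence interval uses the Fisher z transform. With a
#' constant accuracy flag or constant times the correlation is undefined and
#' the result is flagged rather than an error.
#'
#' @param correct Logical/0-1 vector, one flag per showing.
#' @param seconds Numeric vector of anchor seconds within the trial.
#' @param conf Confidence level.
#' @return A `correlation_result`: `r`, `statistic`, `df`, `p`, `ci`,
#'   `n`, `defined`.
#' @export
accuracy_time_correlation <- function(correct, seconds, conf = 0.95) {
  correct <- as.numeric(correct)
  n <- length(correct)
  if (n != length(seconds)) stop("length mismatch", call. = FALSE)
  if (n < 3L) stop("need at least 3 showings", call. = FALSE)
  if (sd(correct) == 0 || sd(seconds) == 0) {
    return(structure(list(r = NA_real_, statistic = NA_real_, df = n - 2,
                          p = NA_real_, ci = c(NA_real_, NA_real_), n = n,
                          defined = FALSE),
                     class = "correlation_result"))
  }
  r <- cor(correct, seconds)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(t), n - 2)
  z <- atanh(r)
  zc <- qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  structure(list(r = r, statistic = t, df = n - 2, p = p,
                 ci = tanh(c(z - zc, z + zc)), n = n, defined = TRUE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (!x$defined) {
    cat("correlation undefined (constant input), n =", x$n, "\n")
  } else {
    cat(sprintf("r = %.4f, t(%d) = %.3f, p = %.4g, 95%% CI [%.4f, %.4f]\n",
                x$r, x$df, x$statistic, x$p, x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' Paired condition comparison of per-type showing frequencies
#'
#' For each showing type, the per-cell counts in the far condition are
#' compared with the matched cells (same pair, trial and phase) of the close
#' condition by a paired t test. Types whose count differences have zero
#' variance are reported as undefined.
#'
#' @param obs Observation table covering both conditions.
#' @return A 15-row data.frame: `type_id`, means per condition, `t`, `df`,
#'   `p`, `d`, `defined`.
#' @export
compare_type_frequencies <- function(obs) {
  key <- function(d) paste(d$pair, d$trial, d$phase)
  far <- obs[obs$condition == "far", , drop = FALSE]
  close <- obs[obs$condition == "close", , drop = FALSE]
  idx <- match(key(far), key(close))
  if (any(is.na(idx))) stop("conditions are not matched cell-for-cell",
                            call. = FALSE)
  close <- close[idx, , drop = FALSE]
  out <- lapply(1:15, function(k) {
    col <- paste0("n_type_", k)
    a <- far[[col]]; b <- close[[col]]
    res <- tryCatch(paired_t(a, b), error = function(e) NULL)
    data.frame(type_id = k, mean_far = mean(a), mean_close = mean(b),
               t = if (is.null(res)) NA_real_ else res$statistic,
               df = if (is.null(res)) NA_real_ else res$df,
               p = if (is.null(res)) NA_real_ else res$p,
               d = if (is.null(res)) NA_real_ else res$d,
               defined = !is.null(res))
  })
  do.call(rbind, out)
}
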