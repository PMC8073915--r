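# Bayesian mixed-effects logistic regression for the decision to cross a
# waterbody versus detour around it:
#
#   cross_i ~ Bernoulli(p_i)
#   logit(p_i) = b0 + b1 * tailwind_s + b2 * ratio_s + b3 * night + u_bird(i)
#   u_b ~ Normal(0, sigma^2)
#
# with weakly informative priors: coefficients Normal(0, 5^2) and
# sigma ~ half-Student-t(3, 0, 2.5). With a few dozen decisions and
# near-separable covariates improper flat priors are fragile; these priors
# are wide relative to any plausible log-odds yet keep the posterior
# proper. Continuous covariates are scaled and centred before fitting.
#
# Inference is an adaptive Metropolis-within-Gibbs sampler: the fixed
# effects update as one multivariate block with a scaled empirical
# covariance proposal, each random intercept and log(sigma) update as
# scalar random walks with acceptance-rate-tuned steps. Adaptation runs
# during warmup only. Convergence is summarised with split-Rhat and
# effective sample sizes.

FIXED_EFFECT_NAMES <- c("Intercept", "Tailwind", "Water:Land", "DayOrNight")

.log_half_t <- function(sigma, df = 3, scale = 2.5) {
  # density of |T|, T ~ t_df scaled: 2/scale * dt(sigma/scale, df)
  log(2) + stats::dt(sigma / scale, df = df, log = TRUE) - log(scale)
}

# one MCMC chain; returns draws matrix (kept iterations x params)
.mcmc_chain <- function(y, X, bird, n_iter, warmup, sigma_prior_scale = 2.5,
                        beta_prior_sd = 5, init_beta = NULL) {
  n <- length(y); p <- ncol(X); B <- max(bird)
  rows_b <- split(seq_len(n), bird)
  beta <- if (is.null(init_beta)) rep(0, p) else init_beta
  u <- rep(0, B); ls <- 0
  eta <- drop(X %*% beta) + u[bird]
  loglik <- function(eta) sum(y * eta - .log1pexp(eta))
  ll <- loglik(eta)
  lp_beta <- sum(stats::dnorm(beta, 0, beta_prior_sd, log = TRUE))

  step_beta <- 0.4; steps_u <- rep(0.8, B); step_ls <- 0.5
  acc_beta <- 0; acc_u <- rep(0, B); acc_ls <- 0; batch <- 0
  chol_prop <- diag(p)
  hist_beta <- matrix(0, warmup, p)

  keep <- matrix(NA_real_, n_iter - warmup, p + B + 1)
  for (it in seq_len(n_iter)) {
    # --- fixed-effect block
    prop <- beta + step_beta * drop(chol_prop %*% stats::rnorm(p))
    eta_p <- drop(X %*% prop) + u[bird]
    ll_p <- loglik(eta_p)
    lp_p <- sum(stats::dnorm(prop, 0, beta_prior_sd, log = TRUE))
    if (log(stats::runif(1)) < ll_p + lp_p - ll - lp_beta) {
      beta <- prop; eta <- eta_p; ll <- ll_p; lp_beta <- lp_p
      acc_beta <- acc_beta + 1
    }
    # --- random intercepts, one scalar walk per bird
    sigma <- exp(ls)
    for (b in seq_len(B)) {
      d <- steps_u[b] * stats::rnorm(1)
      rb <- rows_b[[b]]
      eta_rb <- eta[rb] + d
      dll <- sum(y[rb] * d - .log1pexp(eta_rb) + .log1pexp(eta[rb]))
      dlp <- stats::dnorm(u[b] + d, 0, sigma, log = TRUE) -
             stats::dnorm(u[b], 0, sigma, log = TRUE)
      if (log(stats::runif(1)) < dll + dlp) {
        u[b] <- u[b] + d; eta[rb] <- eta_rb; ll <- ll + dll
        acc_u[b] <- acc_u[b] + 1
      }
    }
    # --- log(sigma) scalar walk (likelihood of y unchanged)
    ls_p <- ls + step_ls * stats::rnorm(1)
    num <- sum(stats::dnorm(u, 0, exp(ls_p), log = TRUE)) +
           .log_half_t(exp(ls_p), scale = sigma_prior_scale) + ls_p
    den <- sum(stats::dnorm(u, 0, exp(ls), log = TRUE)) +
           .log_half_t(exp(ls), scale = sigma_prior_scale) + ls
    if (log(stats::runif(1)) < num - den) { ls <- ls_p; acc_ls <- acc_ls + 1 }

    if (it <= warmup) {
      hist_beta[it, ] <- beta
      batch <- batch + 1
      if (batch == 50) {
        adj <- function(acc) exp(.clip(acc / 50 - 0.3, -0.5, 0.5))
        step_beta <- step_beta * adj(acc_beta)
        steps_u <- steps_u * vapply(acc_u, function(a)
          exp(.clip(a / 50 - 0.44, -0.5, 0.5)), numeric(1))
        step_ls <- step_ls * exp(.clip(acc_ls / 50 - 0.44, -0.5, 0.5))
        if (it >= 200) {
          S <- stats::cov(hist_beta[max(1, it - 400):it, , drop = FALSE])
          ok <- tryCatch({chol_prop <- t(chol(S + diag(1e-6, p))); TRUE},
                         error = function(e) FALSE)
          if (ok) step_beta <- max(step_beta, 0.8)  # rescale for new basis
        }
        acc_beta <- 0; acc_u[] <- 0; acc_ls <- 0; batch <- 0
      }
    } else {
      keep[it - warmup, ] <- c(beta, u, exp(ls))
    }
  }
  keep
}

.split_rhat <- function(draw_list) {
  # split each chain in half -> 2m sequences; classic potential scale
  # reduction on the stacked halves
  halves <- list()
  for (d in draw_list) {
    n2 <- floor(length(d) / 2)
    halves <- c(halves, list(d[seq_len(n2)], d[n2 + seq_len(n2)]))
  }
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars); Bv <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + Bv / n) / W)
}

.ess_bulk <- function(draw_list) {
  sum(vapply(draw_list, function(d) as.numeric(coda::effectiveSize(d)),
             numeric(1)))
}

.ess_tail <- function(draw_list) {
  all <- unlist(draw_list)
  q <- stats::quantile(all, c(0.05, 0.95), names = FALSE)
  ess_ind <- function(thr, lower) {
    sum(vapply(draw_list, function(d) {
      ind <- if (lower) as.numeric(d <= thr) else as.numeric(d >= thr)
      if (stats::var(ind) == 0) length(ind)
      else as.numeric(coda::effectiveSize(ind))
    }, numeric(1)))
  }
  min(ess_ind(q[1], TRUE), ess_ind(q[2], FALSE))
}

#' Fit the Bayesian mixed logistic crossing model
#'
#' Models the probability that a bird at a coastal departure point crosses
#' the waterbody (versus detouring over land) from its tailwind
#' assistance, the water:land distance-savings ratio, whether the flight
#' was initiated at night, and a Normal random intercept per bird.
#' Tailwind and ratio are scaled and centred internally; the raw values
#' are retained in the returned object.
#'
#' @param departures data frame with columns `decision` (`"cross"` /
#'   `"detour"`, or a 0/1 vector `cross`), `tailwind_ms`, `ratio`,
#'   `night` (logical), `bird_id`; at least two birds and both outcomes
#'   present
#' @param chains number of MCMC chains (>= 1; 4 by default)
#' @param iter iterations per chain, first half used as adaptive warmup
#' @param seed integer seed (optional)
#' @param beta_prior_sd prior SD of the coefficients
#' @param sigma_prior_scale scale of the half-Student-t(3) prior on the
#'   random-intercept SD
#' @return a `crossing_fit` object: posterior `draws` (one matrix per
#'   chain), the coefficient `summary` table (Estimate, Est.Error, 95%
#'   credible interval, Rhat, Bulk_ESS, Tail_ESS), the design data and
#'   standardisation constants
#' @seealso [bayes_r2()], [predict.crossing_fit()]
#' @export
fit_crossing_model <- function(departures, chains = 4, iter = 2000,
                               seed = NULL, beta_prior_sd = 5,
                               sigma_prior_scale = 2.5) {
  if (!is.null(seed)) set.seed(seed)
  y <- if ("decision" %in% names(departures)) {
    as.integer(departures$decision == "cross")
  } else as.integer(departures$cross)
  if (all(y == y[1])) .stopf("outcomes are all identical; model not estimable")
  ids <- factor(departures$bird_id)
  if (nlevels(ids) < 2) .stopf("need departures from at least two birds")
  tw_s <- scale_center(departures$tailwind_ms)
  ratio_s <- scale_center(departures$ratio)
  night <- as.numeric(departures$night)
  X <- cbind(Intercept = 1, Tailwind = as.numeric(tw_s),
             `Water:Land` = as.numeric(ratio_s), DayOrNight = night)
  # flag (quasi-)complete separation; the priors keep the fit proper
  for (j in 2:4) {
    lo <- range(X[y == 1, j]); hi <- range(X[y == 0, j])
    if (lo[1] > hi[2] || hi[1] > lo[2])
      message(sprintf("note: covariate '%s' separates the outcomes; ",
                      colnames(X)[j]),
              "priors regularise the fit")
  }
  bird <- as.integer(ids)
  init <- tryCatch(
    suppressWarnings(
      .clip(stats::coef(stats::glm.fit(X, y, family = stats::binomial())),
            -5, 5)),
    error = function(e) rep(0, ncol(X)))
  init[!is.finite(init)] <- 0
  warmup <- floor(iter / 2)
  draws <- lapply(seq_len(chains), function(ch) {
    d <- .mcmc_chain(y, X, bird, n_iter = iter, warmup = warmup,
                     sigma_prior_scale = sigma_prior_scale,
                     beta_prior_sd = beta_prior_sd, init_beta = init)
    colnames(d) <- c(FIXED_EFFECT_NAMES,
                     paste0("u[", levels(ids), "]"), "sigma_bird")
    d
  })
  pars <- colnames(draws[[1]])
  summ <- t(vapply(pars, function(pn) {
    per_chain <- lapply(draws, function(d) d[, pn])
    all <- unlist(per_chain)
    c(Estimate = mean(all), Est.Error = stats::sd(all),
      `l-95% CI` = unname(stats::quantile(all, 0.025)),
      `u-95% CI` = unname(stats::quantile(all, 0.975)),
      Rhat = .split_rhat(per_chain),
      Bulk_ESS = .ess_bulk(per_chain),
      Tail_ESS = .ess_tail(per_chain))
  }, numeric(7)))
  structure(list(draws = draws, summary = summ, y = y, X = X, bird = bird,
                 bird_levels = levels(ids),
                 scaling = list(
                   tailwind = c(attr(tw_s, "center"), attr(tw_s, "scale")),
                   ratio = c(attr(ratio_s, "center"), attr(ratio_s, "scale"))),
                 chains = chains, iter = iter, warmup = warmup),
            class = "crossing_fit")
}

#' Extract stacked posterior draws
#' @param fit a `crossing_fit`
#' @param pars parameter names (default all)
#' @return matrix, all post-warmup draws by parameter
#' @export
posterior_draws <- function(fit, pars = NULL) {
  d <- do.call(rbind, fit$draws)
  if (!is.null(pars)) d <- d[, pars, drop = FALSE]
  d
}

#' @export
coef.crossing_fit <- function(object, ...) {
  object$summary[FIXED_EFFECT_NAMES, "Estimate"]
}

#' @export
print.crossing_fit <- function(x, digits = 2, ...) {
  cat("Bayesian mixed logistic crossing model\n")
  cat(sprintf("  %d departures, %d birds, %d chains x %d iterations (%d warmup)\n",
              length(x$y), length(x$bird_levels), x$chains, x$iter, x$warmup))
  cat("\nPopulation-level effects (logit scale, continuous covariates scaled):\n")
  print(round(x$summary[FIXED_EFFECT_NAMES, , drop = FALSE], digits))
  cat("\nGroup-level effect:\n")
  print(round(x$summary["sigma_bird", , drop = FALSE], digits))
  invisible(x)
}

#' @export
summary.crossing_fit <- function(object, ...) {
  out <- list(coefficients = object$summary,
              r2 = bayes_r2(object),
              n = length(object$y), n_birds = length(object$bird_levels))
  class(out) <- "summary.crossing_fit"
  out
}

#' @export
print.summary.crossing_fit <- function(x, digits = 2, ...) {
  print(round(x$coefficients, digits))
  cat(sprintf("\nBayes R2: %.2f (Est.Error %.2f; CI %.2f-%.2f) on %d departures, %d birds\n",
              x$r2[["mean"]], x$r2[["sd"]], x$r2[["l95"]], x$r2[["u95"]],
              x$n, x$n_birds))
  invisible(x)
}

# linear predictor draws for (possibly new) data
.linpred_draws <- function(fit, newdata = NULL, re = TRUE) {
  d <- posterior_draws(fit)
  if (is.null(newdata)) {
    eta <- d[, FIXED_EFFECT_NAMES] %*% t(fit$X)
    if (re) {
      U <- d[, paste0("u[", fit$bird_levels, "]"), drop = FALSE]
      eta <- eta + U[, fit$bird, drop = FALSE]
    }
    return(eta)
  }
  tw <- (newdata$tailwind_ms - fit$scaling$tailwind[1]) / fit$scaling$tailwind[2]
  ra <- (newdata$ratio - fit$scaling$ratio[1]) / fit$scaling$ratio[2]
  X <- cbind(1, tw, ra, as.numeric(newdata$night))
  eta <- d[, FIXED_EFFECT_NAMES] %*% t(X)
  if (re && "bird_id" %in% names(newdata)) {
    known <- match(as.character(newdata$bird_id), fit$bird_levels)
    U <- d[, paste0("u[", fit$bird_levels, "]"), drop = FALSE]
    add <- matrix(0, nrow(d), nrow(X))
    ok <- !is.na(known)
    add[, ok] <- U[, known[ok], drop = FALSE]
    eta <- eta + add
  }
  eta
}

#' Posterior predicted crossing probabilities
#'
#' @param object a `crossing_fit`
#' @param newdata data frame with `tailwind_ms`, `ratio`, `night` (raw
#'   scales; standardised internally with the training constants) and
#'   optionally `bird_id`; default: the training data
#' @param type `"response"` (probability) or `"link"` (logit)
#' @param re include the bird random intercepts (`TRUE`; unknown birds
#'   get 0, the population level)
#' @param ... unused
#' @return posterior mean prediction per row
#' @export
predict.crossing_fit <- function(object, newdata = NULL,
                                 type = c("response", "link"), re = TRUE, ...) {
  type <- match.arg(type)
  eta <- .linpred_draws(object, newdata, re = re)
  if (type == "link") colMeans(eta) else colMeans(stats::plogis(eta))
}

#' @export
residuals.crossing_fit <- function(object, ...) {
  object$y - predict(object)
}

#' Draw from the posterior predictive distribution of outcomes
#' @param object a `crossing_fit`
#' @param nsim number of posterior-predictive replicates
#' @param seed optional seed
#' @param ... unused
#' @return matrix `nsim` x n of simulated 0/1 outcomes
#' @export
simulate.crossing_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  eta <- .linpred_draws(object)
  idx <- sample.int(nrow(eta), nsim, replace = TRUE)
  p <- stats::plogis(eta[idx, , drop = FALSE])
  matrix(stats::rbinom(length(p), 1, p), nrow = nsim)
}

#' Coefficient interval plot
#' @param x a `crossing_fit`
#' @param ... passed to `plot`
#' @export
plot.crossing_fit <- function(x, ...) {
  s <- x$summary[rev(FIXED_EFFECT_NAMES), , drop = FALSE]
  graphics::plot(s[, "Estimate"], seq_len(nrow(s)),
                 xlim = range(s[, c("l-95% CI", "u-95% CI")]),
                 yaxt = "n", ylab = "", xlab = "Estimate (logit scale)",
                 pch = 19, ...)
  graphics::axis(2, at = seq_len(nrow(s)), labels = rownames(s), las = 1)
  graphics::segments(s[, "l-95% CI"], seq_len(nrow(s)),
                     s[, "u-95% CI"], seq_len(nrow(s)))
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Bayes R-squared of the crossing model
#'
#' Per posterior draw `s`, with fitted probabilities `p_i`:
#' `R2_s = Var_i(p) / (Var_i(p) + mean_i(p (1 - p)))` — the variance of
#' the fitted values over itself plus the expected Bernoulli residual
#' variance. Always in `[0, 1]`.
#'
#' @param fit a `crossing_fit`
#' @return named vector `mean`, `sd`, `l95`, `u95`
#' @export
bayes_r2 <- function(fit) {
  eta <- .linpred_draws(fit)
  p <- stats::plogis(eta)
  vfit <- apply(p, 1, stats::var)
  vres <- rowMeans(p * (1 - p))
  r2 <- vfit / (vfit + vres)
  c(mean = mean(r2), sd = stats::sd(r2),
    l95 = unname(stats::quantile(r2, 0.025)),
    u95 = unname(stats::quantile(r2, 0.975)))
}

#' Linear regression of log flight distance on daylight minutes
#'
#' Ordinary least squares of `log(distance_km + 1)` on the daylight
#' minutes available within each 12-h segment, fitted separately per
#' phase. The +1 km offset accommodates zero-distance segments.
#'
#' @param segments segment table with `daylight_min` (see
#'   [add_daylight()]) and `distance_km`
#' @param phase `"day"` or `"night"`
#' @return a `daylight_fit` with `slope`, its 95% confidence interval,
#'   `intercept`, `n_segments` and the underlying `lm`
#' @export
fit_daylight_regression <- function(segments, phase = c("night", "day")) {
  phase <- match.arg(phase)
  s <- segments[segments$phase == phase & is.finite(segments$daylight_min), ,
                drop = FALSE]
  if (nrow(s) < 3) .stopf("need at least 3 %s segments with daylight", phase)
  if (stats::sd(s$daylight_min) == 0)
    .stopf("daylight is constant; slope not estimable")
  fit <- stats::lm(log(distance_km + 1) ~ daylight_min, data = s)
  ci <- stats::confint(fit, "daylight_min", level = 0.95)
  structure(list(phase = phase,
                 slope = unname(stats::coef(fit)["daylight_min"]),
                 slope_ci = c(ci[1], ci[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_segments = nrow(s), lm = fit),
            class = "daylight_fit")
}

#' @export
print.daylight_fit <- function(x, ...) {
  cat(sprintf(
    "Daylight regression (%s segments, n = %d): slope %.4f [%.4f, %.4f] log-km per minute\n",
    x$phase, x$n_segments, x$slope, x$slope_ci[1], x$slope_ci[2]))
  invisible(x)
}

#' @export
coef.daylight_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}
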