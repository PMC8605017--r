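## Individualized dynamic prediction: conditional recurrence-free
## probabilities pi(u | t) given survival to t and the subject's ctDNA
## history, with Monte-Carlo percentile bands (parameter uncertainty from
## the fit's covariance or posterior draws; random-effect uncertainty from
## parallel Metropolis-Hastings chains on p(b | history, T > t)).
## A deterministic Gauss-Hermite plug-in predictor backs the
## cross-validation harness, where only point predictions are needed.

#' Subject history for dynamic prediction
#'
#' @param day measurement days (surgery = day 0).
#' @param log_ctdna measured log ctDNA levels.
#' @param tp53_mut,t4_stage baseline covariates.
#' @param patient identifier.
#' @return object of class \code{subject_history}.
#' @export
subject_history <- function(day, log_ctdna, tp53_mut, t4_stage,
                            patient = "subject") {
  stopifnot(length(day) == length(log_ctdna))
  if (is.unsorted(day, strictly = FALSE)) {
    o <- order(day); day <- day[o]; log_ctdna <- log_ctdna[o]
  }
  structure(list(patient = patient, day = day, log_ctdna = log_ctdna,
                 tp53_mut = isTRUE(tp53_mut), t4_stage = isTRUE(t4_stage)),
            class = "subject_history")
}

## draw-wise parameter arrays from a jm_fit
.param_draws <- function(fit, n_draws, param_uncertainty, seed_offset = 0L) {
  nm <- names(fit$theta)
  K <- length(fit$cuts)
  if (!param_uncertainty) {
    TH <- matrix(rep(fit$theta, each = n_draws), n_draws,
                 dimnames = list(NULL, nm))
  } else if (!is.null(fit$draws)) {
    TH <- fit$draws[sample.int(nrow(fit$draws), n_draws, replace = TRUE), ,
                    drop = FALSE]
  } else {
    L <- t(chol((fit$vcov + t(fit$vcov)) / 2 + diag(1e-12, length(nm))))
    Z <- matrix(rnorm(n_draws * length(nm)), length(nm), n_draws)
    TH <- t(fit$theta + L %*% Z)
    colnames(TH) <- nm
  }
  unpack1 <- function(th) .theta_unpack(th, fit$association, K)
  ps <- apply(TH, 1, unpack1, simplify = FALSE)
  list(beta0 = vapply(ps, `[[`, 0, "beta0"),
       beta = t(vapply(ps, `[[`, c(0, 0), "beta")),
       sigma = vapply(ps, `[[`, 0, "sigma"),
       D = lapply(ps, `[[`, "D"),
       gamma = t(vapply(ps, `[[`, c(0, 0), "gamma")),
       alpha = t(vapply(ps, function(p) p$alpha, c(0, 0, 0))),
       lograte = t(vapply(ps, function(p) log(p$rates), numeric(K))),
       M = n_draws)
}

## H_m(t | b_m) for every draw m, at a single time t
.H_draws <- function(t, P, B, lp, basis, cuts, gl) {
  if (t <= 0) return(numeric(P$M))
  upper <- c(cuts[-1], Inf)
  A1 <- P$beta[, 1] + B[, 1]   # beta + b, per draw
  A2 <- P$beta[, 2] + B[, 2]
  H <- numeric(P$M)
  for (j in seq_along(cuts)) {
    hi <- min(t, upper[j])
    if (hi <= cuts[j]) break
    g <- gl_rescale(gl, cuts[j], hi)
    N <- suppressWarnings(ncs_eval(basis, g$nodes))
    Nd <- suppressWarnings(ncs_eval(basis, g$nodes, deriv = 1))
    Ni <- ncs_integral(basis, g$nodes)
    ## (nodes x draws) log-hazard
    eta <- outer(N[, 1], A1) + outer(N[, 2], A2) +
      rep(P$beta0, each = length(g$nodes))
    deta <- outer(Nd[, 1], A1) + outer(Nd[, 2], A2)
    ieta <- outer(Ni[, 1], A1) + outer(Ni[, 2], A2) +
      outer(g$nodes, P$beta0)
    lh <- rep(P$lograte[, j], each = length(g$nodes)) +
      rep(lp, each = length(g$nodes)) +
      eta * rep(P$alpha[, 1], each = length(g$nodes)) +
      deta * rep(P$alpha[, 2], each = length(g$nodes)) +
      ieta * rep(P$alpha[, 3], each = length(g$nodes))
    H <- H + colSums(g$weights * exp(pmin(lh, 700)))
  }
  H
}

#' Conditional recurrence-free probability with uncertainty bands
#'
#' Monte-Carlo estimator of \eqn{\pi(u | t) = P(T \ge u \mid T > t,
#' history)}: parameters are drawn from the fit's covariance (or posterior
#' draws), the subject's random effects from parallel Metropolis-Hastings
#' chains targeting p(b | history, T > t), and the median with 2.5/97.5
#' percentile band of S(u|b)/S(t|b) is reported per horizon.
#'
#' @param fit a \code{jm_fit}.
#' @param history a [subject_history()].
#' @param horizons prediction days (all at or after \code{t}).
#' @param t conditioning day; defaults to the last measurement day. Must be
#'   at or after the last measurement.
#' @param n_draws Monte-Carlo draws (parallel chains).
#' @param burn Metropolis-Hastings burn-in steps per chain.
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @param param_uncertainty propagate parameter uncertainty (default TRUE).
#' @return object of class \code{prediction_set}: data.frame with
#'   \code{horizon}, \code{median}, \code{lower}, \code{upper}, \code{mean};
#'   attributes carry \code{t}, \code{n_draws}, \code{seed}.
#' @export
predict_conditional_rfs <- function(fit, history, horizons, t = NULL,
                                    n_draws = 500, burn = 200, seed = 1L,
                                    param_uncertainty = TRUE) {
  stopifnot(inherits(fit, "jm_fit"), inherits(history, "subject_history"))
  n_y <- length(history$day)
  if (is.null(t)) t <- if (n_y > 0) max(history$day) else 0
  if (n_y > 0 && t < max(history$day))
    stop("conditioning time t must be at or after the last measurement")
  if (any(horizons < t)) stop("horizons must be at or after t")
  set.seed(seed)
  if (n_y == 0)
    warning("no measurements: covariate-only prediction (random effects ",
            "constrained only by survival to t)")
  P <- .param_draws(fit, n_draws, param_uncertainty)
  M <- P$M
  lp <- P$gamma[, 1] * history$tp53_mut + P$gamma[, 2] * history$t4_stage
  gl <- gauss_legendre(fit$gl_nodes %||% 7)
  basis <- fit$basis; cuts <- fit$cuts
  ## D inverses per draw
  Di <- vapply(P$D, function(D) {
    di <- solve(D); c(di[1, 1], di[2, 1], di[2, 2],
                      determinant(D, TRUE)$modulus[1])
  }, numeric(4))
  Ny <- if (n_y > 0) ncs_eval(basis, history$day) else matrix(0, 0, 2)
  loglik_b <- function(B) {
    v <- numeric(M)
    if (n_y > 0) {
      eta <- rep(P$beta0, each = n_y) +
        outer(Ny[, 1], P$beta[, 1] + B[, 1]) +
        outer(Ny[, 2], P$beta[, 2] + B[, 2])
      r <- history$log_ctdna - eta
      v <- v - n_y * log(P$sigma) - colSums(r^2) / (2 * P$sigma^2)
    }
    v <- v - .H_draws(t, P, B, lp, basis, cuts, gl)
    q <- Di[1, ] * B[, 1]^2 + 2 * Di[2, ] * B[, 1] * B[, 2] +
      Di[3, ] * B[, 2]^2
    v - 0.5 * Di[4, ] - 0.5 * q
  }
  ## per-draw Gaussian approximation of p(b | y) for init and proposals
  V11 <- V12 <- V22 <- m1 <- m2 <- numeric(M)
  for (m in seq_len(M)) {
    Dinv <- solve(P$D[[m]])
    A <- crossprod(Ny) / P$sigma[m]^2 + Dinv
    V <- solve(A)
    rhs <- if (n_y > 0)
      crossprod(Ny, history$log_ctdna - P$beta0[m] -
                  Ny %*% P$beta[m, ]) / P$sigma[m]^2
    else c(0, 0)
    mm <- drop(V %*% rhs)
    m1[m] <- mm[1]; m2[m] <- mm[2]
    V11[m] <- V[1, 1]; V12[m] <- V[1, 2]; V22[m] <- V[2, 2]
  }
  L11 <- sqrt(V11); L21 <- V12 / L11; L22 <- sqrt(pmax(V22 - L21^2, 1e-12))
  B <- cbind(m1, m2)
  cur <- loglik_b(B)
  sc <- 2.4 / sqrt(2)
  for (s in seq_len(burn)) {
    z1 <- rnorm(M); z2 <- rnorm(M)
    Bp <- B + sc * cbind(L11 * z1, L21 * z1 + L22 * z2)
    prop <- loglik_b(Bp)
    ok <- log(runif(M)) < prop - cur
    B[ok, ] <- Bp[ok, ]
    cur[ok] <- prop[ok]
  }
  Ht <- .H_draws(t, P, B, lp, basis, cuts, gl)
  out <- lapply(horizons, function(u) {
    if (u <= t) return(data.frame(horizon = u, median = 1, lower = 1,
                                  upper = 1, mean = 1))
    pi_m <- pmin(1, pmax(0, exp(-( .H_draws(u, P, B, lp, basis, cuts, gl) - Ht))))
    qs <- quantile(pi_m, c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(horizon = u, median = qs[1], lower = qs[2], upper = qs[3],
               mean = mean(pi_m))
  })
  res <- do.call(rbind, out)
  attr(res, "t") <- t
  attr(res, "n_draws") <- n_draws
  attr(res, "seed") <- seed
  attr(res, "patient") <- history$patient
  class(res) <- c("prediction_set", "data.frame")
  res
}

#' Update a dynamic prediction with new measurements
#'
#' Appends the new measurements to the history, advances the conditioning
#' time to the latest draw, and recomputes the conditional prediction. An
#' empty update reproduces the previous prediction (same seed).
#'
#' @param fit a \code{jm_fit}.
#' @param history a [subject_history()].
#' @param new_measurements data.frame with \code{day}, \code{log_ctdna};
#'   days must exceed the current conditioning time.
#' @param horizons,... passed to [predict_conditional_rfs()].
#' @return a \code{prediction_set}.
#' @export
update_prediction <- function(fit, history, new_measurements, horizons, ...) {
  stopifnot(inherits(history, "subject_history"))
  if (is.null(new_measurements) || nrow(new_measurements) == 0)
    return(predict_conditional_rfs(fit, history, horizons, ...))
  t_old <- if (length(history$day) > 0) max(history$day) else 0
  if (any(new_measurements$day <= t_old))
    stop("new measurement times must exceed the previous conditioning time")
  h2 <- subject_history(c(history$day, new_measurements$day),
                        c(history$log_ctdna, new_measurements$log_ctdna),
                        history$tp53_mut, history$t4_stage, history$patient)
  predict_conditional_rfs(fit, h2, horizons, ...)
}

## ---- deterministic plug-in predictor (used by cross-validation) --------

## pi(u | t0, history) by adaptive Gauss-Hermite integration at theta-hat:
## pi = int f(y|b) phi(b) S(u|b) db / int f(y|b) phi(b) S(t0|b) db
.jm_pi_quad <- function(fit, history, t0, u, gh_nodes = 9) {
  p <- fit$estimates
  basis <- fit$basis; cuts <- fit$cuts
  gl <- gauss_legendre(fit$gl_nodes %||% 7)
  gh <- .gh_grid(gh_nodes)
  n_y <- length(history$day)
  Dinv <- solve(p$D)
  Ny <- if (n_y > 0) ncs_eval(basis, history$day) else matrix(0, 0, 2)
  A <- crossprod(Ny) / p$sigma^2 + Dinv
  V <- solve(A)
  rhs <- if (n_y > 0)
    crossprod(Ny, history$log_ctdna - p$beta0 - Ny %*% p$beta) / p$sigma^2
  else c(0, 0)
  mm <- drop(V %*% rhs)
  L <- t(chol(V))
  Z <- rbind(gh$z1, gh$z2)
  B <- t(mm + sqrt(2) * L %*% Z)          # K x 2 nodes
  K <- nrow(B)
  logf <- gh$logw                          # log w + |z|^2 (constant Jacobian cancels)
  if (n_y > 0) {
    eta <- rep(p$beta0, each = n_y) + outer(Ny[, 1], p$beta[1] + B[, 1]) +
      outer(Ny[, 2], p$beta[2] + B[, 2])
    r <- history$log_ctdna - eta
    logf <- logf - colSums(r^2) / (2 * p$sigma^2)
  }
  q <- Dinv[1, 1] * B[, 1]^2 + 2 * Dinv[2, 1] * B[, 1] * B[, 2] +
    Dinv[2, 2] * B[, 2]^2
  logf <- logf - q / 2
  lp <- sum(p$gamma * c(history$tp53_mut, history$t4_stage))
  ## cumulative hazard at time tt for every quadrature node, vectorised:
  ## (GL nodes x b-nodes) log-hazard matrix per baseline interval
  Hfun <- function(tt) {
    if (tt <= 0) return(numeric(K))
    upper <- c(cuts[-1], Inf)
    A1 <- p$beta[1] + B[, 1]; A2 <- p$beta[2] + B[, 2]
    H <- numeric(K)
    for (j in seq_along(cuts)) {
      hi <- min(tt, upper[j])
      if (hi <= cuts[j]) break
      g <- gl_rescale(gl, cuts[j], hi)
      N <- suppressWarnings(ncs_eval(basis, g$nodes))
      Nd <- suppressWarnings(ncs_eval(basis, g$nodes, deriv = 1))
      Ni <- ncs_integral(basis, g$nodes)
      lh <- log(p$rates[j]) + lp +
        p$alpha[1] * (p$beta0 + outer(N[, 1], A1) + outer(N[, 2], A2)) +
        p$alpha[2] * (outer(Nd[, 1], A1) + outer(Nd[, 2], A2)) +
        p$alpha[3] * (outer(g$nodes, rep(p$beta0, K)) +
                        outer(Ni[, 1], A1) + outer(Ni[, 2], A2))
      H <- H + colSums(g$weights * exp(pmin(lh, 100)))
    }
    H
  }
  Ht <- Hfun(t0)
  Hu <- Hfun(u)
  num <- logsumexp(logf - Hu)
  den <- logsumexp(logf - Ht)
  out <- exp(num - den)
  if (!is.finite(out)) {
    ## degenerate conditioning (survival to t0 numerically impossible at
    ## every node): fall back to the ratio at the best-supported node
    k_star <- which.max(logf - Ht)
    out <- exp(-(Hu[k_star] - Ht[k_star]))
  }
  min(1, max(0, out))
}

#' Deterministic point prediction of conditional recurrence-free probability
#'
#' Plug-in estimator at the fitted parameters: the random effect is
#' integrated by adaptive Gauss-Hermite quadrature given the history and
#' survival to \code{t0}. Fast and deterministic; used by the
#' cross-validation harness (no uncertainty band).
#'
#' @param fit a \code{jm_fit}.
#' @param history a [subject_history()] (measurements at or before
#'   \code{t0}).
#' @param t0 conditioning day.
#' @param u horizon day (\code{u >= t0}).
#' @return scalar probability.
#' @export
predict_rfs_point <- function(fit, history, t0, u) {
  stopifnot(inherits(fit, "jm_fit"), u >= t0)
  if (u == t0) return(1)
  .jm_pi_quad(fit, history, t0, u)
}

## ---- Cox comparators ----------------------------------------------------

## conditional survival from a cox_fit with Breslow baseline:
## S(u | x, T > t0) = exp(-(H0(u) - H0(t0)) exp(x beta))
.cox_cond_surv <- function(fit, H0, x, t0, u) {
  lp <- drop(as.matrix(x) %*% fit$coef)
  exp(-(H0(u) - H0(t0)) * exp(lp))
}

#' Landmark Cox dynamic prediction
#'
#' Fits a Cox model to the subjects still at risk at the landmark, using
#' the last observed ctDNA status at the landmark plus baseline covariates
#' (TP53 status, T stage), and predicts conditional recurrence-free
#' probabilities at the horizons from the Breslow baseline.
#'
#' @param subjects subjects table (see [simulate_joint_cohort()]).
#' @param status data.frame \code{patient}, \code{positive}: ctDNA status
#'   at the landmark (e.g. last observed status; see [ctdna_status_at()]).
#'   Subjects with missing status are excluded.
#' @param landmark landmark day (default 8 months).
#' @param horizons horizon days (default 12 and 15 months).
#' @return object of class \code{cox_predictor}: \code{fit} (a
#'   [cox_fit()]), \code{H0}, \code{landmark}, and \code{predictions}
#'   (patient x horizon probabilities) for the risk set.
#' @export
landmark_cox_predict <- function(subjects, status,
                                 landmark = months_to_days(8),
                                 horizons = months_to_days(c(12, 15))) {
  risk <- subjects[subjects$rfs_day > landmark, , drop = FALSE]
  risk <- merge(risk, status, by = "patient")
  risk <- risk[!is.na(risk$positive), , drop = FALSE]
  if (sum(risk$event == 1) == 0) stop("no events after the landmark")
  x <- cbind(ctdna_pos = as.numeric(risk$positive),
             tp53 = as.numeric(risk$tp53_mut),
             t4 = as.numeric(risk$t4_stage))
  keep <- apply(x, 2, function(col) length(unique(col)) > 1)
  fit <- cox_fit(x[, keep, drop = FALSE], risk$rfs_day, risk$event)
  H0 <- breslow_cumhaz(fit)
  preds <- do.call(rbind, lapply(horizons, function(u) {
    data.frame(patient = risk$patient, horizon = u,
               pi = .cox_cond_surv(fit, H0, x[, keep, drop = FALSE],
                                   landmark, u))
  }))
  structure(list(fit = fit, H0 = H0, landmark = landmark,
                 covariates = colnames(x)[keep], predictions = preds,
                 from_origin = FALSE),
            class = "cox_predictor")
}

#' Static Cox prediction from postsurgical ctDNA status
#'
#' Fits a Cox model from surgery (time 0) with the fixed postsurgical ctDNA
#' status plus baseline covariates; predictions at the horizons are
#' conditioned on being at risk at the landmark but never update with later
#' measurements.
#'
#' @param subjects subjects table.
#' @param postsurgical_status data.frame \code{patient}, \code{positive}.
#' @param landmark conditioning day for the reported probabilities.
#' @param horizons horizon days.
#' @return a \code{cox_predictor} (predictions for the landmark risk set).
#' @export
static_cox_predict <- function(subjects, postsurgical_status,
                               landmark = months_to_days(8),
                               horizons = months_to_days(c(12, 15))) {
  dat <- merge(subjects, postsurgical_status, by = "patient")
  dat <- dat[!is.na(dat$positive), , drop = FALSE]
  if (sum(dat$event == 1) == 0) stop("no events")
  x <- cbind(ctdna_pos = as.numeric(dat$positive),
             tp53 = as.numeric(dat$tp53_mut),
             t4 = as.numeric(dat$t4_stage))
  keep <- apply(x, 2, function(col) length(unique(col)) > 1)
  fit <- cox_fit(x[, keep, drop = FALSE], dat$rfs_day, dat$event)
  H0 <- breslow_cumhaz(fit)
  risk <- dat$rfs_day > landmark
  preds <- do.call(rbind, lapply(horizons, function(u) {
    data.frame(patient = dat$patient[risk], horizon = u,
               pi = .cox_cond_surv(fit, H0,
                                   x[risk, keep, drop = FALSE], landmark, u))
  }))
  structure(list(fit = fit, H0 = H0, landmark = landmark,
                 covariates = colnames(x)[keep], predictions = preds,
                 from_origin = TRUE),
            class = "cox_predictor")
}

#' Last observed ctDNA status at a landmark
#'
#' Per patient, the status of the last sample drawn at or before
#' \code{min(t, observed time)}; NA when no such sample exists.
#'
#' @param series longitudinal table (\code{patient}, \code{day},
#'   \code{positive}).
#' @param subjects subjects table (for the observed time).
#' @param t landmark day.
#' @return data.frame \code{patient}, \code{positive}.
#' @export
ctdna_status_at <- function(series, subjects, t) {
  out <- lapply(subjects$patient, function(pt) {
    lim <- min(t, subjects$rfs_day[subjects$patient == pt])
    s <- series[series$patient == pt & series$day <= lim, , drop = FALSE]
    data.frame(patient = pt,
               positive = if (nrow(s) == 0) NA else
                 s$positive[which.max(s$day)])
  })
  do.call(rbind, out)
}
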