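## Self-contained survival layer: product-limit estimator, log-rank test,
## Cox proportional hazards by Newton-Raphson on the partial likelihood
## (Efron or Breslow ties), Breslow baseline hazard, landmark ctDNA status
## classification and the ctDNA-vs-imaging lead-time analysis.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function with Greenwood standard
#' errors.
#'
#' @param times positive follow-up times (days).
#' @param events event indicator (1/TRUE = event, 0/FALSE = censored).
#' @return object of class \code{km_curve}: a data.frame with one row per
#'   distinct time (\code{time}, \code{n_risk}, \code{n_event},
#'   \code{n_censor}, \code{surv}, \code{se}).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  stopifnot(length(times) == length(events), all(times > 0))
  events <- as.integer(as.logical(events))
  tt <- sort(unique(times))
  n_risk <- vapply(tt, function(u) sum(times >= u), 0)
  n_event <- vapply(tt, function(u) sum(times == u & events == 1), 0)
  n_censor <- vapply(tt, function(u) sum(times == u & events == 0), 0)
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(ifelse(n_risk > n_event,
                      n_event / (n_risk * (n_risk - n_event)), 0))
  se <- surv * sqrt(gw)
  out <- data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, surv = surv, se = se)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve a [km_estimate()] result.
#' @param t times at which to read off the step function (S = 1 before the
#'   first observed time).
#' @return numeric vector of survival probabilities.
#' @export
km_surv_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(u) {
    i <- findInterval(u, curve$time)
    if (i == 0) 1 else curve$surv[i]
  }, 0)
}

#' Log-rank test
#'
#' @param times follow-up times.
#' @param events event indicators.
#' @param group group labels (2 or more groups).
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{observed} and \code{expected} per group.
#' @export
logrank_test <- function(times, events, group) {
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2) stop("need at least 2 groups")
  if (any(table(group) == 0)) stop("empty group")
  events <- as.integer(as.logical(events))
  if (sum(events) < 1) stop("need at least one event")
  ev_times <- sort(unique(times[events == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (u in ev_times) {
    at_risk <- times >= u
    n <- sum(at_risk)
    d <- sum(times == u & events == 1)
    ng <- vapply(levels(group), function(g) sum(at_risk & group == g), 0)
    dg <- vapply(levels(group), function(g)
      sum(times == u & events == 1 & group == g), 0)
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      w <- d * (n - d) / (n - 1)
      V <- V + w * (diag(ng / n, k) - outer(ng / n, ng / n))
    }
  }
  idx <- seq_len(k - 1)
  oe <- (O - E)[idx]
  stat <- drop(t(oe) %*% solve(V[idx, idx, drop = FALSE], oe))
  list(statistic = stat, df = k - 1,
       p_value = pchisq(stat, df = k - 1, lower.tail = FALSE),
       observed = O, expected = E)
}

## Efron/Breslow negative partial log-likelihood with gradient and Hessian.
## Data must be pre-sorted by time; loops over distinct event times.
.cox_pl <- function(beta, x, times, events, ties) {
  n <- nrow(x); p <- ncol(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ll <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  ev_times <- unique(times[events == 1])
  for (u in ev_times) {
    R <- which(times >= u)
    D <- which(times == u & events == 1)
    d <- length(D)
    s0r <- sum(w[R])
    s1r <- drop(crossprod(w[R], x[R, , drop = FALSE]))
    s2r <- crossprod(x[R, , drop = FALSE] * w[R], x[R, , drop = FALSE])
    s0d <- sum(w[D])
    s1d <- drop(crossprod(w[D], x[D, , drop = FALSE]))
    s2d <- crossprod(x[D, , drop = FALSE] * w[D], x[D, , drop = FALSE])
    ll <- ll + sum(eta[D])
    U <- U + colSums(x[D, , drop = FALSE])
    frac <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
    for (l in seq_len(d)) {
      s0 <- s0r - frac[l] * s0d
      s1 <- s1r - frac[l] * s1d
      s2 <- s2r - frac[l] * s2d
      ll <- ll - log(s0)
      U <- U - s1 / s0
      I <- I + s2 / s0 - tcrossprod(s1 / s0)
    }
  }
  list(loglik = ll, score = U, info = I)
}

#' Cox proportional hazards regression
#'
#' Newton-Raphson maximisation of the partial likelihood with Efron
#' (default) or Breslow handling of tied event times. Returns Wald,
#' likelihood-ratio and score tests; the score test at beta = 0 coincides
#' with the log-rank test for a single binary covariate without ties.
#'
#' @param x covariate matrix (or data.frame coerced to numeric matrix).
#' @param times follow-up times.
#' @param events event indicators.
#' @param ties "efron" or "breslow".
#' @param maxit,tol Newton-Raphson controls.
#' @return object of class \code{cox_fit} with coefficients, covariance,
#'   hazard ratios with 95\% CI, p-values and the data needed for the
#'   Breslow baseline.
#' @export
cox_fit <- function(x, times, events, ties = c("efron", "breslow"),
                    maxit = 50, tol = 1e-9) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  events <- as.integer(as.logical(events))
  stopifnot(nrow(x) == length(times), length(times) == length(events))
  if (any(apply(x, 2, function(col) length(unique(col)) == 1)))
    stop("covariate constant across all subjects")
  p <- ncol(x)
  if (sum(events) < p) stop("fewer events than covariates")
  ord <- order(times)
  x <- x[ord, , drop = FALSE]; times <- times[ord]; events <- events[ord]
  xc <- sweep(x, 2, colMeans(x))  # centering for numerical stability
  ## ridge-guarded solve: near-separation makes the information singular
  rsolve <- function(A, b) {
    tryCatch(solve(A, b), error = function(e)
      solve(A + diag(1e-8 * max(diag(A), 1), nrow(A)), b))
  }
  beta <- numeric(p)
  pl0 <- .cox_pl(beta, xc, times, events, ties)
  ll0 <- pl0$loglik
  score_stat <- drop(t(pl0$score) %*% rsolve(pl0$info, pl0$score))
  converged <- FALSE
  monotone <- FALSE
  ll_old <- ll0
  for (it in seq_len(maxit)) {
    pl <- .cox_pl(beta, xc, times, events, ties)
    step <- rsolve(pl$info, pl$score)
    ## step-halving if the likelihood decreases
    h <- 1
    repeat {
      cand <- beta + h * step
      llc <- .cox_pl(cand, xc, times, events, ties)$loglik
      if (llc >= pl$loglik - 1e-12 || h < 1 / 64) break
      h <- h / 2
    }
    beta <- beta + h * step
    if (abs(llc - ll_old) < tol * (abs(ll_old) + tol)) { converged <- TRUE; break }
    ll_old <- llc
  }
  if (!converged)
    stop("cox_fit did not converge in ", maxit,
         " iterations (last beta = ", paste(signif(beta, 4), collapse = ", "), ")")
  if (any(abs(beta) > 15)) monotone <- TRUE
  final <- .cox_pl(beta, xc, times, events, ties)
  vcov <- tryCatch(solve(final$info), error = function(e) {
    warning("singular information matrix; ridge-stabilised covariance")
    solve(final$info + diag(1e-8 * max(diag(final$info), 1), p))
  })
  se <- sqrt(diag(vcov))
  z <- beta / se
  lr <- 2 * (final$loglik - ll0)
  nm <- colnames(x) %||% paste0("x", seq_len(p))
  out <- list(coef = setNames(beta, nm), vcov = vcov, se = setNames(se, nm),
              hr = exp(beta),
              hr_ci = cbind(lower = exp(beta - 1.96 * se),
                            upper = exp(beta + 1.96 * se)),
              p_wald = 2 * pnorm(-abs(z)),
              lr_stat = lr, p_lr = pchisq(lr, p, lower.tail = FALSE),
              score_stat = score_stat,
              p_score = pchisq(score_stat, p, lower.tail = FALSE),
              loglik = c(null = ll0, final = final$loglik),
              n = length(times), n_event = sum(events),
              iterations = it, converged = converged,
              monotone_likelihood = monotone, ties = ties,
              x_center = colMeans(x),
              data = list(x = x, times = times, events = events))
  if (monotone)
    warning("possible monotone partial likelihood (complete separation)")
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox PH fit (", x$ties, " ties): n = ", x$n, ", events = ", x$n_event,
      "\n", sep = "")
  print(data.frame(coef = x$coef, HR = x$hr, lower95 = x$hr_ci[, 1],
                   upper95 = x$hr_ci[, 2], p = x$p_wald))
  invisible(x)
}

#' Breslow baseline cumulative hazard
#'
#' Baseline cumulative hazard (at covariate value zero) from a [cox_fit()].
#'
#' @param fit a \code{cox_fit} object.
#' @return function \code{H0(t)} vectorised over \code{t}.
#' @export
breslow_cumhaz <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  x <- fit$data$x; times <- fit$data$times; events <- fit$data$events
  ## risk scores on the uncentered scale
  w <- exp(drop(x %*% fit$coef))
  ev_times <- sort(unique(times[events == 1]))
  dH <- vapply(ev_times, function(u)
    sum(times == u & events == 1) / sum(w[times >= u]), 0)
  H <- cumsum(dH)
  function(t) {
    i <- findInterval(t, ev_times)
    c(0, H)[i + 1]
  }
}

#' Landmark ctDNA status classification
#'
#' Classifies each subject's ctDNA status at the landmarks used in the
#' analysis layer: \code{postsurgical} (sample within one month of surgery
#' and before the start of adjuvant chemotherapy), \code{post_act} (sample
#' within four months after the end of ACT) and \code{longitudinal}
#' (positive if any surveillance sample is positive). Months are converted
#' at 30.44 days. A missing window yields \code{NA} and the subject drops
#' out of that landmark analysis; samples after the recurrence date are
#' excluded with a warning.
#'
#' @param subjects data.frame with columns \code{patient},
#'   \code{act_received}, \code{act_start_day}, \code{act_end_day},
#'   \code{rfs_day}, \code{event}.
#' @param plasma data.frame with columns \code{patient}, \code{day},
#'   \code{positive} (plasma call results).
#' @param rule how multiple in-window samples define status: the
#'   \code{"latest"} pre-treatment sample (default; closest to the treatment
#'   decision) or \code{"any"} positive.
#' @return data.frame: \code{patient}, \code{postsurgical}, \code{post_act},
#'   \code{longitudinal} (logical, NA when the window has no sample).
#' @export
classify_landmark_status <- function(subjects, plasma,
                                     rule = c("latest", "any")) {
  rule <- match.arg(rule)
  month <- DAYS_PER_MONTH
  post_event <- merge(plasma, subjects[, c("patient", "rfs_day")],
                      by = "patient")
  drop_n <- sum(post_event$day > post_event$rfs_day)
  if (drop_n > 0)
    warning(drop_n, " sample(s) after the recurrence/censoring date excluded")
  status_in <- function(days, pos) {
    if (length(days) == 0) return(NA)
    if (rule == "any") any(pos) else pos[which.max(days)]
  }
  out <- lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    p <- plasma[plasma$patient == s$patient & plasma$day <= s$rfs_day, ]
    in_ps <- p$day > 0 & p$day <= month &
      (!isTRUE(s$act_received) | is.na(s$act_start_day) |
         p$day < s$act_start_day)
    ps <- status_in(p$day[in_ps], p$positive[in_ps])
    pa <- NA
    if (isTRUE(s$act_received) && !is.na(s$act_end_day)) {
      in_pa <- p$day > s$act_end_day & p$day <= s$act_end_day + 4 * month
      pa <- status_in(p$day[in_pa], p$positive[in_pa])
    }
    lg <- if (nrow(p) == 0) NA else any(p$positive)
    data.frame(patient = s$patient, postsurgical = ps, post_act = pa,
               longitudinal = lg)
  })
  do.call(rbind, out)
}

#' Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test. Exact p-value by dynamic
#' programming over sign assignments (valid under ties) for n of 25 or
#' fewer non-zero values; normal approximation with tie correction and
#' continuity correction otherwise. Zeros are dropped.
#'
#' @param x numeric vector (e.g. paired differences).
#' @param mu null location (default 0).
#' @return list with \code{statistic} (W, sum of positive ranks), \code{n}
#'   (non-zero values used), \code{p_value} and \code{method}.
#' @export
signed_rank_test <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, n = 0, p_value = 1,
                          method = "degenerate"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    ## exact: distribution of W over all 2^n sign assignments via
    ## convolution on the doubled (integer) rank scale
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1); f[1] <- 1     # f[v+1] = #assignments with 2W = v
    for (ri in r2) {
      g <- numeric(tot + 1)
      g[(ri + 1):(tot + 1)] <- f[1:(tot + 1 - ri)]
      f <- f + g
    }
    vals <- 0:tot
    center <- tot / 2
    w2 <- round(2 * W)
    p <- sum(f[abs(vals - center) >= abs(w2 - center) - 1e-9]) / 2^n
    list(statistic = W, n = n, p_value = min(1, p), method = "exact")
  } else {
    mu_w <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu_w - sign(W - mu_w) * 0.5) / sqrt(sig2)
    list(statistic = W, n = n, p_value = min(1, 2 * pnorm(-abs(z))),
         method = "normal approximation")
  }
}

#' Lead time from ctDNA positivity to radiological recurrence
#'
#' For patients with both a first ctDNA-positive draw and a confirmed
#' radiological recurrence, computes lead = recurrence day - first positive
#' day and tests it against zero with the two-sided Wilcoxon signed-rank
#' test.
#'
#' @param first_positive_day day of first ctDNA-positive sample per patient.
#' @param recurrence_day day of radiological recurrence per patient (paired).
#' @return list with \code{lead_days}, \code{median_lead}, \code{p_value},
#'   \code{n}.
#' @export
lead_time_analysis <- function(first_positive_day, recurrence_day) {
  stopifnot(length(first_positive_day) == length(recurrence_day))
  keep <- complete.cases(first_positive_day, recurrence_day)
  if (!any(keep)) stop("no complete pairs")
  lead <- recurrence_day[keep] - first_positive_day[keep]
  ts <- signed_rank_test(lead)
  list(lead_days = lead, median_lead = median(lead),
       p_value = ts$p_value, n = length(lead))
}
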