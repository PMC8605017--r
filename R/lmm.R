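## Longitudinal sub-model: linear mixed model for log ctDNA level with a
## fixed intercept and 2-df natural cubic spline, and correlated random
## effects on the two spline coefficients (so fixed- and random-effect
## structures match). Maximum likelihood via lme4; empirical Bayes modes and
## conditional covariances seed the adaptive quadrature of the joint fit.

#' Fit the longitudinal (linear mixed) sub-model
#'
#' @param series data.frame with \code{patient}, \code{day},
#'   \code{log_ctdna}.
#' @param basis an [ncs_basis()]; measurements are the log ctDNA levels.
#' @param subjects optional subjects table; when given, measurements at or
#'   after the subject's observed event/censoring time are excluded.
#' @return object of class \code{lmm_submodel}: fixed effects (\code{beta0},
#'   \code{beta}), \code{sigma}, random-effects covariance \code{D},
#'   empirical Bayes modes \code{ranef} and conditional covariances
#'   \code{cond_cov} per subject, \code{loglik}, plus the model frame keys.
#' @export
fit_lmm <- function(series, basis, subjects = NULL) {
  stopifnot(inherits(basis, "ncs_basis"))
  df <- series
  if (!is.null(subjects)) {
    m <- merge(df, subjects[, c("patient", "rfs_day")], by = "patient")
    df <- m[m$day < m$rfs_day, , drop = FALSE]
  }
  if (nrow(df) < 10) stop("too few longitudinal measurements")
  N <- ncs_eval(basis, df$day)
  dat <- data.frame(y = df$log_ctdna, n1 = N[, 1], n2 = N[, 2],
                    patient = factor(df$patient))
  fit <- lme4::lmer(y ~ n1 + n2 + (0 + n1 + n2 | patient), data = dat,
                    REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  lme4::.makeCC("warning", tol = 1e-4)))
  vc <- lme4::VarCorr(fit)
  D <- as.matrix(vc$patient)[1:2, 1:2]
  if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
    warning("near-singular random-effects covariance; ridge applied")
    D <- D + diag(1e-6 * max(1, mean(diag(D))), 2)
  }
  sigma <- stats::sigma(fit)
  fe <- lme4::fixef(fit)
  re <- lme4::ranef(fit, condVar = TRUE)$patient
  pv <- attr(re, "postVar")
  lev <- rownames(re)
  cond <- lapply(seq_along(lev), function(i) pv[, , i])
  names(cond) <- lev
  structure(list(beta0 = unname(fe[1]), beta = unname(fe[2:3]),
                 sigma = sigma, D = unname(D),
                 ranef = as.matrix(re), cond_cov = cond,
                 patients = lev, loglik = as.numeric(logLik(fit)),
                 n_obs = nrow(dat), basis = basis, lme4_fit = fit),
            class = "lmm_submodel")
}

#' @export
print.lmm_submodel <- function(x, ...) {
  cat("spline LMM: beta0 =", signif(x$beta0, 4),
      "; beta =", paste(signif(x$beta, 4), collapse = ", "),
      "; sigma =", signif(x$sigma, 4), "\n")
  cat("D:\n"); print(signif(x$D, 4))
  invisible(x)
}
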