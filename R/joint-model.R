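## Joint model of longitudinal log ctDNA level and time to recurrence.
##
## Longitudinal sub-model: y_ij = eta_i(t_ij) + e_ij,
##   eta_i(t) = beta0 + N(t) (beta + b_i),  b_i ~ N(0, D),  e ~ N(0, sigma^2)
## with N(t) a 2-df natural cubic spline basis.
## Survival sub-model: h_i(t) = h0(t) exp{ gamma1 TP53_i + gamma2 Tstage_i
##   + alpha1 eta_i(t) + alpha2 eta_i'(t) + alpha3 int_0^t eta_i(s) ds }
## with h0 piecewise-constant. Association structures: current value
## (alpha1), value + slope (alpha1, alpha2), value + cumulative area
## (alpha1, alpha3).
##
## The marginal likelihood integrates b_i by adaptive Gauss-Hermite
## quadrature centered at the Gaussian posterior mode of b_i given that
## subject's measurements (pseudo-adaptive: centers use the longitudinal
## data only, recomputed at the current parameter value). Hazard integrals
## use Gauss-Legendre per baseline interval; the spline's closed-form
## antiderivative makes the cumulative association exact.

.JM_ASSOC <- c("value", "value+slope", "value+auc")

## static data blocks reused by every likelihood evaluation
.jm_blocks <- function(subjects, series, basis, cuts, gl_nodes = 7) {
  n <- nrow(subjects)
  idx <- setNames(seq_len(n), subjects$patient)
  ser <- merge(series, subjects[, c("patient", "rfs_day")], by = "patient")
  ser <- ser[ser$day < ser$rfs_day, , drop = FALSE]
  ## canonical row order: results invariant to the input row order
  ser <- ser[order(match(ser$patient, subjects$patient), ser$day), ,
             drop = FALSE]
  stopifnot(nrow(ser) > 0)
  yi <- idx[ser$patient]
  Ny <- ncs_eval(basis, ser$day)
  ## per-subject sufficient statistics for the adaptive centers
  agg <- function(v) {
    out <- numeric(n)
    r <- rowsum(v, yi)
    out[as.integer(rownames(r))] <- r
    out
  }
  ZtZ11 <- agg(Ny[, 1]^2); ZtZ12 <- agg(Ny[, 1] * Ny[, 2]); ZtZ22 <- agg(Ny[, 2]^2)
  Zt1_1 <- agg(Ny[, 1]); Zt1_2 <- agg(Ny[, 2])
  Zty_1 <- agg(Ny[, 1] * ser$log_ctdna); Zty_2 <- agg(Ny[, 2] * ser$log_ctdna)
  ## Gauss-Legendre nodes per subject and baseline interval
  gl <- gauss_legendre(gl_nodes)
  Tt <- subjects$rfs_day
  upper <- c(cuts[-1], Inf)
  nd <- vector("list", n)
  for (i in seq_len(n)) {
    segs <- lapply(seq_along(cuts), function(j) {
      hi <- min(Tt[i], upper[j])
      if (hi <= cuts[j]) return(NULL)
      g <- gl_rescale(gl, cuts[j], hi)
      data.frame(subj = i, s = g$nodes, w = g$weights, rate_idx = j)
    })
    nd[[i]] <- do.call(rbind, segs)
  }
  nd <- do.call(rbind, nd)
  Nn <- suppressWarnings(ncs_eval(basis, nd$s))
  Ndn <- suppressWarnings(ncs_eval(basis, nd$s, deriv = 1))
  Nin <- ncs_integral(basis, nd$s)
  NT <- suppressWarnings(ncs_eval(basis, Tt))
  NdT <- suppressWarnings(ncs_eval(basis, Tt, deriv = 1))
  NiT <- ncs_integral(basis, Tt)
  w_cov <- cbind(as.numeric(subjects$tp53_mut), as.numeric(subjects$t4_stage))
  list(n = n, patients = subjects$patient,
       y = ser$log_ctdna, y_subj0 = as.integer(yi - 1L), Ny = Ny,
       ZtZ = cbind(ZtZ11, ZtZ12, ZtZ22), Zt1 = cbind(Zt1_1, Zt1_2),
       Zty = cbind(Zty_1, Zty_2),
       nd_subj0 = as.integer(nd$subj - 1L), nd_s = nd$s, nd_w = nd$w,
       nd_rate = nd$rate_idx, Nn = Nn, Ndn = Ndn, Nin = Nin,
       Tt = Tt, delta = as.integer(subjects$event),
       T_rate = findInterval(Tt, cuts), NT = NT, NdT = NdT, NiT = NiT,
       w_cov = w_cov, cuts = cuts, n_rates = length(cuts),
       n_obs = nrow(ser))
}

.gh_grid <- function(gh_nodes) {
  g <- gauss_hermite(gh_nodes)
  z <- expand.grid(z1 = g$nodes, z2 = g$nodes)
  lw <- log(expand.grid(w1 = g$weights, w2 = g$weights))
  list(z1 = z$z1, z2 = z$z2,
       logw = lw$w1 + lw$w2 + z$z1^2 + z$z2^2)
}

## theta <-> natural parameters. Layout:
## beta0, beta1, beta2, log sigma, log-Cholesky of D (l1, l21, l2),
## gamma1, gamma2, free alphas (per association), log baseline rates.
.theta_names <- function(association, n_rates) {
  al <- switch(association, value = "alpha1",
               `value+slope` = c("alpha1", "alpha2"),
               `value+auc` = c("alpha1", "alpha3"))
  c("beta0", "beta1", "beta2", "log_sigma", "ld1", "ld21", "ld2",
    "gamma1", "gamma2", al, paste0("log_rate", seq_len(n_rates)))
}

.theta_unpack <- function(theta, association, n_rates) {
  theta <- unname(theta)
  beta0 <- theta[1]; beta <- theta[2:3]
  sigma <- exp(theta[4])
  Ld <- matrix(c(exp(theta[5]), theta[6], 0, exp(theta[7])), 2, 2)
  D <- Ld %*% t(Ld)
  gamma <- theta[8:9]
  alpha <- c(0, 0, 0)
  k <- 9
  alpha[1] <- theta[k + 1]
  if (association == "value+slope") alpha[2] <- theta[k + 2]
  if (association == "value+auc") alpha[3] <- theta[k + 2]
  n_al <- if (association == "value") 1 else 2
  rates <- exp(theta[(k + n_al + 1):(k + n_al + n_rates)])
  list(beta0 = beta0, beta = beta, sigma = sigma, D = D, gamma = gamma,
       alpha = alpha, rates = rates)
}

.theta_pack <- function(p, association) {
  Ld <- t(chol(p$D))
  al <- switch(association, value = p$alpha[1],
               `value+slope` = p$alpha[1:2],
               `value+auc` = p$alpha[c(1, 3)])
  c(p$beta0, p$beta, log(p$sigma), log(Ld[1, 1]), Ld[2, 1], log(Ld[2, 2]),
    p$gamma, al, log(p$rates))
}

## Gaussian posterior center/scale of b_i given that subject's measurements
.adaptive_centers <- function(blocks, beta0, beta, sigma, Dinv) {
  s2 <- sigma^2
  A11 <- blocks$ZtZ[, 1] / s2 + Dinv[1, 1]
  A12 <- blocks$ZtZ[, 2] / s2 + Dinv[1, 2]
  A22 <- blocks$ZtZ[, 3] / s2 + Dinv[2, 2]
  det_A <- A11 * A22 - A12^2
  V11 <- A22 / det_A; V12 <- -A12 / det_A; V22 <- A11 / det_A
  r1 <- (blocks$Zty[, 1] - beta0 * blocks$Zt1[, 1] -
           blocks$ZtZ[, 1] * beta[1] - blocks$ZtZ[, 2] * beta[2]) / s2
  r2 <- (blocks$Zty[, 2] - beta0 * blocks$Zt1[, 2] -
           blocks$ZtZ[, 2] * beta[1] - blocks$ZtZ[, 3] * beta[2]) / s2
  m1 <- V11 * r1 + V12 * r2
  m2 <- V12 * r1 + V22 * r2
  L11 <- sqrt(V11)
  L21 <- V12 / L11
  L22 <- sqrt(pmax(V22 - L21^2, 1e-12))
  list(m1 = m1, m2 = m2, L11 = L11, L21 = L21, L22 = L22)
}

## per-subject log-integrand g_i(b) evaluated at arbitrary b (one point per
## subject), via the single-node quadrature grid
.g_at_b <- function(p, blocks, B) {
  n <- blocks$n
  one <- rep(1, n); zero <- rep(0, n)
  gh1 <- list(z1 = 0, z2 = 0, logw = 0)
  centers <- list(m1 = B[, 1], m2 = B[, 2], L11 = one, L21 = zero, L22 = one)
  .jm_loglik_core(p, blocks, gh1, centers = centers) - log(2)
}

## true adaptive quadrature centers: per-subject Newton ascent on the full
## integrand (longitudinal density x survival x random-effects prior), with
## scales from the curvature at the mode. All subjects are iterated
## simultaneously through vectorised integrand evaluations.
.full_mode_centers <- function(p, blocks, init, iters = 8, h = 1e-3) {
  B <- cbind(init$m1, init$m2)
  g <- .g_at_b(p, blocks, B)
  n <- blocks$n
  e1 <- cbind(rep(h, n), 0); e2 <- cbind(0, rep(h, n))
  H11 <- H12 <- H22 <- rep(-1, n)
  for (it in seq_len(iters)) {
    g1p <- .g_at_b(p, blocks, B + e1); g1m <- .g_at_b(p, blocks, B - e1)
    g2p <- .g_at_b(p, blocks, B + e2); g2m <- .g_at_b(p, blocks, B - e2)
    gpp <- .g_at_b(p, blocks, B + e1 + e2)
    d1 <- (g1p - g1m) / (2 * h); d2 <- (g2p - g2m) / (2 * h)
    H11 <- (g1p - 2 * g + g1m) / h^2
    H22 <- (g2p - 2 * g + g2m) / h^2
    H12 <- (gpp - g1p - g2p + g) / h^2
    det <- H11 * H22 - H12^2
    nd <- is.finite(det) & det > 0 & H11 < 0
    s1 <- ifelse(nd, -(H22 * d1 - H12 * d2) / det, 0.3 * sign(d1))
    s2 <- ifelse(nd, -(-H12 * d1 + H11 * d2) / det, 0.3 * sign(d2))
    ## cap the step to keep the ascent stable
    nrm <- sqrt(s1^2 + s2^2)
    shr <- ifelse(nrm > 3, 3 / nrm, 1)
    step <- cbind(s1 * shr, s2 * shr)
    Bn <- B + step
    gn <- .g_at_b(p, blocks, Bn)
    half <- !is.finite(gn) | gn < g - 1e-10
    if (any(half)) {
      Bh <- B + 0.5 * step
      gh_ <- .g_at_b(p, blocks, Bh)
      use <- half & is.finite(gh_) & gh_ > g
      Bn[use, ] <- Bh[use, ]; gn[use] <- gh_[use]
      keep <- half & !use
      Bn[keep, ] <- B[keep, ]; gn[keep] <- g[keep]
    }
    moved <- max(abs(Bn - B))
    B <- Bn; g <- gn
    if (moved < 1e-6 && it > 2) break
  }
  det <- H11 * H22 - H12^2
  nd <- is.finite(det) & det > 0 & H11 < 0
  V11 <- ifelse(nd, -H22 / det, init$L11^2)
  V12 <- ifelse(nd, H12 / det, init$L21 * init$L11)
  V22 <- ifelse(nd, -H11 / det, init$L21^2 + init$L22^2)
  L11 <- sqrt(pmax(V11, 1e-10))
  L21 <- V12 / L11
  L22 <- sqrt(pmax(V22 - L21^2, 1e-10))
  list(m1 = B[, 1], m2 = B[, 2], L11 = L11, L21 = L21, L22 = L22)
}

## per-subject marginal log-likelihood (optionally with the analytic
## gradient over the full parameter layout) at natural parameters p.
## centers: quadrature centers/scales; NULL recomputes them from p
## (adaptive). During optimisation the caller freezes them so that the
## objective and its analytic gradient are exactly consistent.
.jm_loglik_core <- function(p, blocks, gh, centers = NULL,
                            want_grad = FALSE) {
  Dinv <- solve(p$D)
  logdetD <- determinant(p$D, logarithm = TRUE)$modulus[1]
  ac <- centers
  if (is.null(ac)) {
    ac <- .adaptive_centers(blocks, p$beta0, p$beta, p$sigma, Dinv)
    ac <- .full_mode_centers(p, blocks, ac)
  }
  Ld <- t(chol(p$D))
  logrates <- log(p$rates)
  y_resid_fix <- blocks$y - p$beta0 - drop(blocks$Ny %*% p$beta)
  nd_eta_fix <- p$beta0 + drop(blocks$Nn %*% p$beta)
  nd_deta_fix <- drop(blocks$Ndn %*% p$beta)
  nd_ieta_fix <- p$beta0 * blocks$nd_s + drop(blocks$Nin %*% p$beta)
  T_eta_fix <- p$beta0 + drop(blocks$NT %*% p$beta)
  T_deta_fix <- drop(blocks$NdT %*% p$beta)
  T_ieta_fix <- p$beta0 * blocks$Tt + drop(blocks$NiT %*% p$beta)
  lp <- drop(blocks$w_cov %*% p$gamma)
  res <- jm_loglik_subjects(
    blocks$n, blocks$y_subj0, y_resid_fix, blocks$Ny[, 1], blocks$Ny[, 2],
    p$sigma,
    blocks$nd_subj0, blocks$nd_w, blocks$nd_s,
    as.integer(blocks$nd_rate - 1L), logrates[blocks$nd_rate],
    nd_eta_fix, nd_deta_fix, nd_ieta_fix,
    blocks$Nn[, 1], blocks$Nn[, 2], blocks$Ndn[, 1], blocks$Ndn[, 2],
    blocks$Nin[, 1], blocks$Nin[, 2],
    blocks$delta, blocks$Tt, as.integer(blocks$T_rate - 1L),
    logrates[blocks$T_rate],
    T_eta_fix, T_deta_fix, T_ieta_fix,
    blocks$NT[, 1], blocks$NT[, 2], blocks$NdT[, 1], blocks$NdT[, 2],
    blocks$NiT[, 1], blocks$NiT[, 2],
    blocks$w_cov[, 1], blocks$w_cov[, 2], lp,
    p$alpha[1], p$alpha[2], p$alpha[3],
    Dinv[1, 1], Dinv[2, 1], Dinv[2, 2], logdetD,
    log(Ld[1, 1]), Ld[2, 1], log(Ld[2, 2]),
    ac$m1, ac$m2, ac$L11, ac$L21, ac$L22,
    gh$z1, gh$z2, gh$logw, want_grad)
  if (want_grad) res else res$loglik
}

## map the full C++ gradient layout onto the free theta vector
.grad_select <- function(grad_full, association, n_rates) {
  idx <- switch(association,
                value = c(1:9, 10),
                `value+slope` = c(1:9, 10, 11),
                `value+auc` = c(1:9, 10, 12))
  c(grad_full[idx], grad_full[12 + seq_len(n_rates)])
}

.as_cohort_data <- function(data) {
  if (inherits(data, "synthetic_cohort"))
    list(subjects = data$subjects, series = data$series,
         basis = data$basis)
  else list(subjects = data$subjects, series = data$series,
            basis = data$basis %||% NULL)
}

#' Joint model marginal log-likelihood
#'
#' Integrates each subject's random effects by adaptive Gauss-Hermite
#' quadrature; hazard integrals by Gauss-Legendre per baseline interval.
#' With all association parameters zero this factorises exactly into the
#' mixed-model marginal likelihood plus a parametric proportional-hazards
#' likelihood.
#'
#' @param params list with \code{beta0}, \code{beta} (length 2),
#'   \code{sigma}, \code{D} (2x2), \code{gamma} (length 2), \code{alpha}
#'   (length 3: value, slope, cumulative), \code{rates} (baseline, per
#'   interval).
#' @param data a \code{synthetic_cohort} or list with \code{subjects} and
#'   \code{series}.
#' @param basis [ncs_basis()] of the trajectory.
#' @param cuts baseline-hazard interval start times (first 0).
#' @param association which alpha components are active; components outside
#'   the chosen structure are forced to zero ("custom" keeps \code{alpha}
#'   as given).
#' @param gh_nodes Gauss-Hermite nodes per random-effect dimension.
#' @param gl_nodes Gauss-Legendre nodes per baseline interval.
#' @param per_subject return the per-subject vector instead of the sum.
#' @return scalar log-likelihood (or per-subject vector).
#' @export
joint_log_likelihood <- function(params, data, basis, cuts,
                                 association = c("custom", .JM_ASSOC),
                                 gh_nodes = 9, gl_nodes = 7,
                                 per_subject = FALSE) {
  association <- match.arg(association)
  if (association == "value") params$alpha[2:3] <- 0
  if (association == "value+slope") params$alpha[3] <- 0
  if (association == "value+auc") params$alpha[2] <- 0
  d <- .as_cohort_data(data)
  blocks <- .jm_blocks(d$subjects, d$series, basis, cuts, gl_nodes)
  gh <- .gh_grid(gh_nodes)
  ll <- .jm_loglik_core(params, blocks, gh)
  if (any(!is.finite(ll)))
    stop("non-finite likelihood contribution for subject(s): ",
         paste(blocks$patients[!is.finite(ll)], collapse = ", "))
  if (per_subject) setNames(ll, blocks$patients) else sum(ll)
}

## Two-stage starting values: spline LMM, then a naive Cox fit on the
## baseline covariates plus the empirical-Bayes trajectory features at the
## observed time (value / slope / cumulative area, per the association
## structure), and crude piecewise-exponential rates. The naive Cox places
## the alpha start inside the right likelihood basin; the joint fit then
## corrects its measurement-error attenuation.
.jm_init <- function(blocks, subjects, series, basis, association) {
  lmm <- fit_lmm(series, basis, subjects)
  b_hat <- matrix(0, blocks$n, 2)
  idx <- match(blocks$patients, lmm$patients)
  ok <- !is.na(idx)
  b_hat[ok, ] <- lmm$ranef[idx[ok], , drop = FALSE]
  a_hat <- sweep(b_hat, 2, lmm$beta, "+")
  etaT <- lmm$beta0 + rowSums(blocks$NT * a_hat)
  detaT <- rowSums(blocks$NdT * a_hat)
  ietaT <- lmm$beta0 * blocks$Tt + rowSums(blocks$NiT * a_hat)
  X <- cbind(tp53 = blocks$w_cov[, 1], t4 = blocks$w_cov[, 2], etaT = etaT)
  if (association == "value+slope") X <- cbind(X, detaT = detaT)
  if (association == "value+auc") X <- cbind(X, ietaT = ietaT)
  keep <- apply(X, 2, function(col) length(unique(col)) > 1)
  gamma <- c(0, 0)
  alpha <- c(0, 0, 0)
  cx <- try(cox_fit(X[, keep, drop = FALSE], subjects$rfs_day,
                    subjects$event),
            silent = TRUE)
  if (!inherits(cx, "try-error") && !cx$monotone_likelihood) {
    cf <- setNames(numeric(ncol(X)), colnames(X))
    cf[keep] <- cx$coef
    gamma <- unname(cf[1:2])
    alpha[1] <- unname(cf["etaT"])
    if (association == "value+slope") alpha[2] <- unname(cf["detaT"])
    if (association == "value+auc") alpha[3] <- unname(cf["ietaT"])
    ## keep the start well inside the box bounds
    gamma <- pmin(pmax(gamma, -5), 5)
    alpha <- pmin(pmax(alpha, c(-8, -8, -0.3)), c(8, 8, 0.3))
  }
  cuts <- blocks$cuts
  upper <- c(cuts[-1], Inf)
  lp0 <- drop(blocks$w_cov %*% gamma) + alpha[1] * etaT +
    alpha[2] * detaT + alpha[3] * ietaT
  mean_rr <- mean(exp(pmin(lp0, 50)))
  rates <- vapply(seq_along(cuts), function(j) {
    pt <- sum(pmax(0, pmin(subjects$rfs_day, upper[j]) - cuts[j]))
    dj <- sum(subjects$event == 1 & subjects$rfs_day > cuts[j] &
                subjects$rfs_day <= upper[j])
    max(dj, 0.5) / max(pt, 1) / mean_rr
  }, 0)
  p <- list(beta0 = lmm$beta0, beta = lmm$beta, sigma = max(lmm$sigma, 1e-3),
            D = lmm$D + diag(1e-8, 2), gamma = gamma,
            alpha = alpha, rates = pmax(rates, 1e-10))
  list(theta = .theta_pack(p, association), lmm = lmm)
}

#' Fit the joint model
#'
#' Two-stage initialisation (spline LMM + covariate-only Cox), then either
#' quasi-Newton maximisation of the marginal likelihood with
#' observed-information covariance (\code{engine = "map_ml"}, default;
#' deterministic) or random-walk Metropolis posterior sampling with
#' weakly-informative priors (\code{engine = "mcmc"}): normal(0, 10^2) on
#' fixed effects, log hazard ratios and association parameters, half-t(3)
#' on the residual and random-effect SDs, normal(0, 10^2) on the
#' off-diagonal Cholesky term and on log baseline rates.
#'
#' @param data \code{synthetic_cohort} or list with \code{subjects},
#'   \code{series}.
#' @param association one of "value", "value+slope", "value+auc" (the
#'   current-value plus cumulative-area structure is the default final
#'   model).
#' @param engine "map_ml" or "mcmc".
#' @param basis optional [ncs_basis()]; default boundary knots at 0 and the
#'   95th percentile of measurement days, interior knot at the median.
#' @param baseline_intervals piecewise-constant baseline intervals (cut at
#'   event-time quantiles).
#' @param gh_nodes,gl_nodes quadrature sizes.
#' @param seed integer seed (drives the MCMC engine; map_ml is
#'   deterministic).
#' @param init optional starting parameter list (as in
#'   [joint_log_likelihood()]).
#' @param control list: \code{maxit} (default 500), \code{reltol}
#'   (1e-10), \code{n_iter}/\code{burn} for MCMC (4000/1000).
#' @return object of class \code{jm_fit}.
#' @export
fit_joint_model <- function(data, association = c("value+auc", "value",
                                                  "value+slope"),
                            engine = c("map_ml", "mcmc"),
                            basis = NULL, baseline_intervals = 5,
                            gh_nodes = 9, gl_nodes = 7, seed = 1L,
                            init = NULL, control = list()) {
  association <- match.arg(association)
  engine <- match.arg(engine)
  set.seed(seed)
  d <- .as_cohort_data(data)
  subjects <- d$subjects; series <- d$series
  if (is.null(basis)) basis <- d$basis
  if (is.null(basis)) basis <- ncs_basis(series$day)
  ev <- subjects$rfs_day[subjects$event == 1]
  if (length(ev) < 5) stop("too few events to anchor the baseline hazard")
  K <- baseline_intervals
  cuts <- unname(c(0, quantile(ev, seq_len(K - 1) / K)))
  cuts <- sort(unique(cuts))
  blocks <- .jm_blocks(subjects, series, basis, cuts, gl_nodes)
  gh <- .gh_grid(gh_nodes)
  nm <- .theta_names(association, length(cuts))
  two_stage <- .jm_init(blocks, subjects, series, basis, association)
  theta0 <- if (is.null(init)) two_stage$theta
            else .theta_pack(init, association)
  ## freeze the quadrature centers (full-integrand modes and curvatures at
  ## the two-stage estimates) so the objective and its analytic gradient
  ## are exactly consistent during optimisation
  p0 <- .theta_unpack(theta0, association, length(cuts))
  centers <- .full_mode_centers(
    p0, blocks, .adaptive_centers(blocks, p0$beta0, p0$beta, p0$sigma,
                                  solve(p0$D)))
  cache <- new.env(parent = emptyenv())
  evals <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta))
      return(cache$res)
    p <- .theta_unpack(theta, association, length(cuts))
    res <- tryCatch(.jm_loglik_core(p, blocks, gh, centers = centers,
                                    want_grad = TRUE),
                    error = function(e) NULL)
    if (is.null(res) || !all(is.finite(res$loglik)))
      res <- list(loglik = -1e10 / blocks$n * rep(1, blocks$n),
                  grad = rep(0, 12 + length(cuts)))
    cache$theta <- theta
    cache$res <- res
    res
  }
  negll <- function(theta) -sum(evals(theta)$loglik)
  neggr <- function(theta)
    -.grad_select(evals(theta)$grad, association, length(cuts))
  ctrl <- list(maxit = control$maxit %||% 500,
               factr = control$factr %||% 1e7)
  ## generous box bounds keep the search out of regions where fixed-center
  ## quadrature breaks down (they never bind at a legitimate optimum)
  bnd <- function(nm) switch(sub("[0-9]+$", "", nm),
    beta = c(-50, 50), log_sigma = c(-5, 3), ld = c(-5, 4),
    gamma = c(-4, 4), alpha = c(-4, 4), log_rate = c(-20, 0),
    c(-Inf, Inf))
  lower <- vapply(nm, function(x) bnd(x)[1], 0)
  upper <- vapply(nm, function(x) bnd(x)[2], 0)
  lower[nm == "ld21"] <- -20; upper[nm == "ld21"] <- 20
  lower[nm == "alpha3"] <- -0.05; upper[nm == "alpha3"] <- 0.05
  ## optimise with adaptation passes (re-center the quadrature at the
  ## current optimum, repeat), then certify the solution: the log-likelihood
  ## at the optimum must be stable under quadrature refinement. Association
  ## parameters can wander into regions where the survival factor is a
  ## near-discontinuous cliff in b-space; there fixed-grid quadrature is
  ## unreliable and can manufacture spurious optima, which the refinement
  ## check detects. Unstable solutions trigger a restart from a damped
  ## initialisation.
  ai <- grep("^alpha", nm)
  run_opt <- function(start) {
    ## stage A: associations held at their two-stage starting values, so the
    ## remaining (nearly separable) parameters settle first; stage B frees
    ## everything. This path-following keeps iterates away from the
    ## degenerate ridge where large alphas absorb the baseline hazard.
    la <- lower; ua <- upper
    la[ai] <- ua[ai] <- start[ai]
    opA <- optim(start, negll, neggr, method = "L-BFGS-B",
                 lower = la, upper = ua, control = ctrl)
    op <- optim(opA$par, negll, neggr, method = "L-BFGS-B",
                lower = lower, upper = upper, control = ctrl)
    if (op$convergence == 1)  # maxit: continue from where it stopped
      op <- optim(op$par, negll, neggr, method = "L-BFGS-B",
                  lower = lower, upper = upper, control = ctrl)
    for (pass in seq_len(control$adapt_passes %||% 3)) {
      p1 <- .theta_unpack(op$par, association, length(cuts))
      centers <<- .full_mode_centers(
        p1, blocks, .adaptive_centers(blocks, p1$beta0, p1$beta, p1$sigma,
                                      solve(p1$D)))
      cache$theta <- NULL
      ll_rec <- -negll(op$par)
      op2 <- optim(op$par, negll, neggr, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = ctrl)
      moved <- max(abs(op2$par - op$par))
      drift <- abs(-op2$value - ll_rec)
      op <- op2
      if (moved < 1e-5 && drift < 1e-3) break
    }
    op
  }
  quad_stable <- function(theta) {
    p1 <- .theta_unpack(theta, association, length(cuts))
    cen <- .full_mode_centers(
      p1, blocks, .adaptive_centers(blocks, p1$beta0, p1$beta, p1$sigma,
                                    solve(p1$D)))
    ll9 <- sum(.jm_loglik_core(p1, blocks, gh, centers = cen))
    ll25 <- sum(.jm_loglik_core(p1, blocks, .gh_grid(25), centers = cen))
    abs(ll9 - ll25)
  }
  opt <- run_opt(theta0)
  quad_err <- quad_stable(opt$par)
  tries <- 0
  while ((quad_err > (control$quad_tol %||% 2) || opt$convergence != 0) &&
         tries < 2) {
    tries <- tries + 1
    damp <- theta0
    ## first retry: halve the association start; second: drop it to zero
    damp[ai] <- if (tries == 1) damp[ai] * 0.5 else 0
    damp[-ai] <- damp[-ai] + (0.02 * tries) * (seq_along(damp[-ai]) %% 2 - 0.5)
    p0 <- .theta_unpack(damp, association, length(cuts))
    centers <- .full_mode_centers(
      p0, blocks, .adaptive_centers(blocks, p0$beta0, p0$beta, p0$sigma,
                                    solve(p0$D)))
    cache$theta <- NULL
    cand <- run_opt(damp)
    cand_err <- quad_stable(cand$par)
    better <- (cand_err <= (control$quad_tol %||% 2) &&
                 cand$convergence == 0) ||
      (quad_err > (control$quad_tol %||% 2) && cand_err < quad_err)
    if (better) { opt <- cand; quad_err <- cand_err }
  }
  if (opt$convergence != 0) {
    ## a maxit exit at a numerically stationary point is still a solution
    gmax <- max(abs(neggr(opt$par)))
    if (opt$convergence == 1 && gmax < 0.1) {
      warning("iteration cap reached at an effectively stationary point ",
              "(max |gradient| = ", signif(gmax, 3), ")")
    } else if (isTRUE(control$best_effort)) {
      warning("joint model not fully converged (code ", opt$convergence,
              ", max |gradient| ", signif(gmax, 4),
              "); best-effort estimates returned")
    } else {
      stop("joint model did not converge (code ", opt$convergence,
           "); last value ", signif(opt$value, 8), "; max |gradient| ",
           signif(gmax, 4), "; theta = ",
           paste(signif(opt$par, 4), collapse = ", "))
    }
  }
  if (quad_err > (control$quad_tol %||% 2))
    warning("quadrature-unstable optimum (refinement shifts logLik by ",
            signif(quad_err, 3), "); estimates may be unreliable")
  theta_hat <- setNames(opt$par, nm)
  ## observed information: symmetrised central differences of the gradient
  h <- 1e-4
  Pn <- length(theta_hat)
  H <- matrix(0, Pn, Pn)
  for (j in seq_len(Pn)) {
    tp <- theta_hat; tp[j] <- tp[j] + h
    tm <- theta_hat; tm[j] <- tm[j] - h
    H[, j] <- (neggr(tp) - neggr(tm)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  vc <- try(solve(H), silent = TRUE)
  if (inherits(vc, "try-error") || any(!is.finite(vc)) ||
      any(diag(vc) <= 0)) {
    warning("observed information not positive definite; ",
            "ridge-stabilised covariance")
    e <- eigen((H + t(H)) / 2, symmetric = TRUE)
    vals <- pmax(e$values, 1e-8 * max(abs(e$values)))
    vc <- e$vectors %*% diag(1 / vals) %*% t(e$vectors)
  }
  dimnames(vc) <- list(nm, nm)
  est <- .theta_unpack(theta_hat, association, length(cuts))
  fit <- list(theta = theta_hat, vcov = vc, estimates = est,
              association = association, engine = engine,
              basis = basis, cuts = cuts,
              loglik = -opt$value,
              aic = 2 * opt$value + 2 * length(theta_hat),
              n = blocks$n, n_event = sum(blocks$delta),
              n_obs = blocks$n_obs,
              gh_nodes = gh_nodes, gl_nodes = gl_nodes,
              seed = seed,
              convergence = list(code = opt$convergence,
                                 counts = opt$counts,
                                 engine = "map_ml"))
  class(fit) <- "jm_fit"
  if (engine == "mcmc") {
    mc <- .jm_mcmc(fit, blocks, gh, association, cuts, nm,
                   n_iter = control$n_iter %||% 4000,
                   burn = control$burn %||% 1000, seed = seed)
    fit$draws <- mc$draws
    fit$rhat <- mc$rhat
    fit$accept_rate <- mc$accept_rate
    th_med <- apply(mc$draws, 2, median)
    fit$theta <- setNames(th_med, nm)
    fit$estimates <- .theta_unpack(th_med, association, length(cuts))
    fit$vcov <- stats::cov(mc$draws)
    dimnames(fit$vcov) <- list(nm, nm)
    fit$convergence$engine <- "mcmc"
    if (any(mc$rhat > 1.1, na.rm = TRUE))
      warning("MCMC split-Rhat > 1.1 for: ",
              paste(nm[mc$rhat > 1.1], collapse = ", "))
  }
  fit
}

## weakly-informative log-prior on the working scale (includes Jacobians)
.jm_logprior <- function(theta, association, n_rates) {
  p <- .theta_unpack(theta, association, n_rates)
  half_t <- function(s, log_s) dt(s / 2.5, df = 3, log = TRUE) -
    log(2.5) + log(2) + log_s
  sum(dnorm(c(p$beta0, p$beta, p$gamma), 0, 10, log = TRUE)) +
    sum(dnorm(theta[grep("^alpha", names(theta))], 0, 10, log = TRUE)) +
    half_t(p$sigma, theta[4]) +
    half_t(exp(theta[5]), theta[5]) + half_t(exp(theta[7]), theta[7]) +
    dnorm(theta[6], 0, 10, log = TRUE) +
    sum(dnorm(log(p$rates), 0, 10, log = TRUE))
}

.jm_mcmc <- function(fit, blocks, gh, association, cuts, nm,
                     n_iter, burn, seed) {
  set.seed(seed + 1L)
  p_dim <- length(fit$theta)
  ## quadrature centers frozen at the MAP point: every iteration then costs
  ## a single likelihood evaluation and the target is a fixed approximation
  pm <- .theta_unpack(fit$theta, association, length(cuts))
  centers <- .full_mode_centers(
    pm, blocks, .adaptive_centers(blocks, pm$beta0, pm$beta, pm$sigma,
                                  solve(pm$D)))
  logpost <- function(theta) {
    names(theta) <- nm
    p <- .theta_unpack(theta, association, length(cuts))
    v <- tryCatch(sum(.jm_loglik_core(p, blocks, gh, centers = centers)),
                  error = function(e) -Inf)
    if (!is.finite(v)) return(-Inf)
    v + .jm_logprior(theta, association, length(cuts))
  }
  S <- fit$vcov
  Lp <- t(chol((S + t(S)) / 2 + diag(1e-10, p_dim)))
  scale <- 2.38 / sqrt(p_dim)
  cur <- unname(fit$theta)
  cur_lp <- logpost(cur)
  draws <- matrix(NA_real_, n_iter - burn, p_dim)
  acc <- 0
  for (it in seq_len(n_iter)) {
    prop <- cur + scale * drop(Lp %*% rnorm(p_dim))
    lp_prop <- logpost(prop)
    if (log(runif(1)) < lp_prop - cur_lp) {
      cur <- prop; cur_lp <- lp_prop; acc <- acc + 1
    }
    if (it <= burn && it %% 50 == 0) {  # Robbins-Monro toward 0.25
      rate <- acc / it
      scale <- scale * exp(0.5 * (rate - 0.25))
    }
    if (it > burn) draws[it - burn, ] <- cur
  }
  colnames(draws) <- nm
  ## split-Rhat over 4 segments of the kept chain
  nseg <- 4
  seg <- split(seq_len(nrow(draws)),
               cut(seq_len(nrow(draws)), nseg, labels = FALSE))
  rhat <- vapply(seq_len(p_dim), function(j) {
    mseg <- vapply(seg, function(ii) mean(draws[ii, j]), 0)
    vseg <- vapply(seg, function(ii) var(draws[ii, j]), 0)
    W <- mean(vseg); B <- var(mseg) * length(seg[[1]])
    if (W <= 0) return(NA_real_)
    sqrt((W * (1 - 1 / length(seg[[1]])) + B / length(seg[[1]])) / W)
  }, 0)
  list(draws = draws, rhat = setNames(rhat, nm),
       accept_rate = acc / n_iter)
}

#' @export
print.jm_fit <- function(x, ...) {
  cat("joint model fit (", x$association, ", ", x$convergence$engine,
      "): n = ", x$n, ", events = ", x$n_event, ", logLik = ",
      signif(x$loglik, 8), "\n", sep = "")
  e <- x$estimates
  cat("  beta0 =", signif(e$beta0, 4),
      "beta =", paste(signif(e$beta, 4), collapse = ", "),
      "sigma =", signif(e$sigma, 4), "\n")
  cat("  gamma =", paste(signif(e$gamma, 4), collapse = ", "),
      " alpha =", paste(signif(e$alpha, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Wald confidence intervals for identity-scale joint-model parameters
#'
#' @param fit a \code{jm_fit}.
#' @param level confidence level.
#' @return data.frame with estimate, se, lower, upper for beta0, beta,
#'   gamma and the active alphas.
#' @export
jm_confint <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "jm_fit"))
  keep <- grep("^(beta|gamma|alpha)", names(fit$theta), value = TRUE)
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(fit$vcov)[keep])
  est <- fit$theta[keep]
  data.frame(parameter = keep, estimate = unname(est), se = unname(se),
             lower = unname(est - z * se), upper = unname(est + z * se))
}

#' Compare association structures
#'
#' Fits the three candidate hazard-association structures (current value;
#' value + slope; value + cumulative area) on the same data and basis and
#' ranks them by cross-validated dynamic AUROC (default), cross-validated
#' prediction error, or AIC.
#'
#' @param data cohort data.
#' @param candidates subset of the three structures.
#' @param criterion "cv_auc", "cv_pe" or "aic".
#' @param landmark,horizon evaluation window in days (used by the CV
#'   criteria).
#' @param k,repeats,seed cross-validation settings.
#' @param ... passed to [fit_joint_model()].
#' @return list with \code{ranking} (data.frame, best first), \code{fits},
#'   \code{criterion}; failed candidates carry NA and rank last.
#' @export
compare_association_structures <- function(data, candidates = .JM_ASSOC,
                                           criterion = c("cv_auc", "cv_pe",
                                                         "aic"),
                                           landmark = months_to_days(8),
                                           horizon = months_to_days(12),
                                           k = 5, repeats = 2, seed = 1L,
                                           ...) {
  criterion <- match.arg(criterion)
  candidates <- match.arg(candidates, .JM_ASSOC, several.ok = TRUE)
  fits <- lapply(candidates, function(a)
    tryCatch(fit_joint_model(data, association = a, seed = seed, ...),
             error = function(e) e))
  names(fits) <- candidates
  score <- rep(NA_real_, length(candidates))
  for (j in seq_along(candidates)) {
    if (inherits(fits[[j]], "error")) next
    if (criterion == "aic") {
      score[j] <- -fits[[j]]$aic  # higher is better
    } else {
      spec <- jm_model_spec(association = candidates[j], ...)
      cv <- repeated_kfold_cv(data, specs = setNames(list(spec), candidates[j]),
                              k = k, repeats = repeats,
                              windows = list(c(landmark, horizon)),
                              seed = seed)
      metric <- if (criterion == "cv_auc") "AUROC" else "PE"
      vals <- cv$value[cv$metric == metric]
      score[j] <- if (criterion == "cv_auc") median(vals, na.rm = TRUE)
                  else -median(vals, na.rm = TRUE)
    }
  }
  ranking <- data.frame(association = candidates, score = score,
                        failed = vapply(fits, inherits, TRUE, "error"))
  ranking <- ranking[order(-ranking$score, na.last = TRUE), ]
  ranking$rank <- seq_len(nrow(ranking))
  list(ranking = ranking, fits = fits, criterion = criterion)
}

#' Serialise a joint-model fit to JSON
#'
#' Stores everything predictions need (parameters, covariance, knots,
#' baseline cuts, association, seed) so they are reproducible across
#' processes.
#'
#' @param fit a \code{jm_fit}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_jm_fit <- function(fit, path) {
  stopifnot(inherits(fit, "jm_fit"))
  obj <- list(package_version = as.character(packageVersion("ctdnaJM")),
              theta = as.list(fit$theta), vcov = fit$vcov,
              association = fit$association, engine = fit$engine,
              knots = fit$basis$knots, cuts = fit$cuts,
              loglik = fit$loglik, n = fit$n, seed = fit$seed,
              gh_nodes = fit$gh_nodes, gl_nodes = fit$gl_nodes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a joint-model fit from JSON
#'
#' @param path file written by [write_jm_fit()].
#' @return a \code{jm_fit} (sufficient for prediction).
#' @export
read_jm_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kn <- obj$knots
  basis <- ncs_basis(knots = kn[-c(1, length(kn))],
                     boundary = kn[c(1, length(kn))])
  theta <- unlist(obj$theta)
  vc <- as.matrix(obj$vcov)
  dimnames(vc) <- list(names(theta), names(theta))
  est <- .theta_unpack(theta, obj$association, length(obj$cuts))
  structure(list(theta = theta, vcov = vc, estimates = est,
                 association = obj$association, engine = obj$engine,
                 basis = basis, cuts = obj$cuts, loglik = obj$loglik,
                 n = obj$n, seed = obj$seed, gh_nodes = obj$gh_nodes,
                 gl_nodes = obj$gl_nodes,
                 convergence = list(engine = obj$engine)),
            class = "jm_fit")
}
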