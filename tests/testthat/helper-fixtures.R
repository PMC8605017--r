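# Shared fixtures, built in code (no stored data).

# tiny read-family table builder: one row per read
fam_rows <- function(contig = "chr1", pos, umiA, umiB, orientation, alleles) {
  data.frame(contig = contig, pos = pos, umiA = umiA, umiB = umiB,
             orientation = orientation, read_idx = seq_along(alleles),
             allele = alleles)
}

# minimal background db entry
db_row <- function(pos, ref = "A", alt = "T", rate = 1e-5,
                   contig = "chr1") {
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt, rate = rate,
             max_support = 1, n_samples = 10)
}

# construct a jm_fit object directly from known parameters (no fitting);
# used by prediction oracles where the parameters must be exact
manual_jm_fit <- function(beta0, beta, sigma, D, gamma, alpha, rates, cuts,
                          basis, association = "custom") {
  p <- list(beta0 = beta0, beta = beta, sigma = sigma, D = D, gamma = gamma,
            alpha = alpha, rates = rates)
  assoc <- if (association == "custom") "value+auc" else association
  theta <- ctdnaJM:::.theta_pack(p, assoc)
  nm <- ctdnaJM:::.theta_names(assoc, length(cuts))
  fit <- list(theta = setNames(theta, nm),
              vcov = diag(1e-12, length(theta)),
              estimates = p, association = assoc, engine = "map_ml",
              basis = basis, cuts = cuts, loglik = NA_real_, n = NA,
              gh_nodes = 9, gl_nodes = 7,
              convergence = list(engine = "map_ml"))
  class(fit) <- "jm_fit"
  fit
}

# three-subject toy cohort for likelihood oracles: hand-picked measurement
# times, levels, covariates and outcomes
toy3_cohort <- function() {
  subjects <- data.frame(
    patient = c("T1", "T2", "T3"),
    tp53_mut = c(TRUE, FALSE, TRUE),
    t4_stage = c(FALSE, FALSE, TRUE),
    stage = "II",
    act_received = FALSE, act_start_day = NA_real_, act_end_day = NA_real_,
    rfs_day = c(300, 500, 640),
    event = c(1L, 0L, 1L))
  series <- data.frame(
    patient = rep(c("T1", "T2", "T3"), times = c(3, 4, 4)),
    day = c(0, 91, 183,   0, 91, 183, 274,   0, 91, 274, 457),
    log_ctdna = c(1.2, 2.0, 3.1,   0.4, -0.2, 0.3, 0.1,   1.5, 2.4, 3.3, 4.1))
  basis <- ncs_basis(knots = 365, boundary = c(0, 730))
  list(subjects = subjects, series = series, basis = basis)
}

toy3_params <- function() {
  list(beta0 = 0.5, beta = c(1.2, 1.6), sigma = 0.6,
       D = matrix(c(2.5, 0.4, 0.4, 1.2), 2, 2),
       gamma = c(0.8, 0.5), alpha = c(0.3, 0, 0.0015),
       rates = c(4e-4, 8e-4, 6e-4),
       cuts = c(0, 200, 450))
}

# independent dense-grid oracle for the per-subject joint likelihood and
# for conditional survival: plain R, trapezoid grid over b, its own hazard
# integration on a fine time grid (no reuse of package quadrature helpers)
oracle_subject_loglik <- function(p, basis, cuts, sub, ser, ngrid = 161,
                                  span = 6, tgrid_n = 4000) {
  Dk <- p$D
  sd1 <- sqrt(Dk[1, 1]); sd2 <- sqrt(Dk[2, 2])
  b1g <- seq(-span * sd1, span * sd1, length.out = ngrid)
  b2g <- seq(-span * sd2, span * sd2, length.out = ngrid)
  Ny <- ncs_eval(basis, ser$day)
  lp <- sum(p$gamma * c(sub$tp53_mut, sub$t4_stage))
  Tt <- sub$rfs_day
  tg <- seq(0, Tt, length.out = tgrid_n)
  dt <- tg[2] - tg[1]
  Ntg <- ncs_eval(basis, tg)
  Itg <- ncs_integral(basis, tg)
  h0tg <- p$rates[findInterval(tg, cuts)]
  NT <- ncs_eval(basis, Tt); IT <- ncs_integral(basis, Tt)
  h0T <- p$rates[findInterval(Tt, cuts)]
  Dinv <- solve(Dk)
  vals <- matrix(NA_real_, ngrid, ngrid)
  for (i1 in seq_len(ngrid)) for (i2 in seq_len(ngrid)) {
    b <- c(b1g[i1], b2g[i2])
    a <- p$beta + b
    mu <- p$beta0 + drop(Ny %*% a)
    ll_y <- sum(dnorm(ser$log_ctdna, mu, p$sigma, log = TRUE))
    eta_t <- p$beta0 + drop(Ntg %*% a)
    ieta_t <- p$beta0 * tg + drop(Itg %*% a)
    lh <- log(h0tg) + lp + p$alpha[1] * eta_t + p$alpha[3] * ieta_t
    H <- sum(exp(lh)) * dt - 0.5 * (exp(lh[1]) + exp(lh[length(lh)])) * dt
    log_h_T <- log(h0T) + lp + p$alpha[1] * (p$beta0 + drop(NT %*% a)) +
      p$alpha[3] * (p$beta0 * Tt + drop(IT %*% a))
    ll_s <- sub$event * log_h_T - H
    ll_b <- -log(2 * pi) - 0.5 * determinant(Dk)$modulus[1] -
      0.5 * drop(t(b) %*% Dinv %*% b)
    vals[i1, i2] <- ll_y + ll_s + ll_b
  }
  mx <- max(vals)
  mx + log(sum(exp(vals - mx)) * (b1g[2] - b1g[1]) * (b2g[2] - b2g[1]))
}
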