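## Synthetic cohort generator: the generative inverse of the joint model.
## Subject-specific log ctDNA trajectories follow a natural-cubic-spline
## linear mixed model; recurrence hazards multiply a piecewise-constant
## baseline by covariate effects (TP53, T stage) and by the trajectory's
## current value, slope and/or cumulative area. Event times are drawn by
## inverting the subject's cumulative hazard. Also simulates UMI read
## families for the MRD caller.

#' Piecewise-constant cumulative hazard
#'
#' @param t times (vector).
#' @param cuts interval start times, first must be 0; the last rate extends
#'   to infinity.
#' @param rates hazard rates per interval (events/day), same length as cuts.
#' @return cumulative hazard at \code{t}.
#' @export
pch_cumhaz <- function(t, cuts, rates) {
  stopifnot(length(cuts) == length(rates), cuts[1] == 0, all(rates >= 0))
  upper <- c(cuts[-1], Inf)
  H <- numeric(length(t))
  for (j in seq_along(cuts))
    H <- H + rates[j] * pmax(0, pmin(t, upper[j]) - cuts[j])
  H
}

#' Piecewise-exponential survival function
#'
#' @inheritParams pch_cumhaz
#' @return survival probability at \code{t}.
#' @export
pch_survival <- function(t, cuts, rates) exp(-pch_cumhaz(t, cuts, rates))

## invert H(t) = target for a piecewise-constant hazard (closed form)
pch_invert <- function(target, cuts, rates) {
  upper <- c(cuts[-1], Inf)
  Hlow <- c(0, cumsum(rates[-length(rates)] * diff(cuts)))
  vapply(target, function(h) {
    for (j in seq_along(cuts)) {
      width <- upper[j] - cuts[j]
      Hhi <- if (is.finite(width)) Hlow[j] + rates[j] * width else
        (if (rates[j] > 0) Inf else Hlow[j])
      if (h <= Hhi + 1e-15 && rates[j] > 0)
        return(cuts[j] + (h - Hlow[j]) / rates[j])
    }
    Inf
  }, 0)
}

#' Simulation parameters for the synthetic cohort
#'
#' Defaults describe a resected-NSCLC-like world: quarterly draws over two
#' years with an additional postsurgical draw at day 14, log ctDNA level on
#' the Gaussian working scale starting below the detection offset and rising
#' in relapsing subjects, covariate log hazard ratios at the univariately
#' reported magnitudes (TP53 3.3, T4 stage 2.7), a current-value plus
#' cumulative-area association, a baseline hazard peaking around nine months
#' after surgery scaled for a roughly 35\% two-year event rate, and 5\%
#' per-visit dropout independent of the trajectory.
#'
#' @param n_subjects number of subjects.
#' @param beta0 fixed intercept of the log ctDNA trajectory.
#' @param beta fixed-effect coefficients on the 2-df natural spline basis.
#' @param D 2x2 random-effects covariance (on the spline coefficients).
#' @param sigma residual SD of measured log ctDNA level.
#' @param gamma1,gamma2 log hazard ratios for TP53 mutation and T4 stage.
#' @param alpha1,alpha2,alpha3 association of the hazard with the current
#'   trajectory value, its slope, and its running integral (per
#'   log-level-day).
#' @param baseline list with \code{cuts} (starting at 0) and \code{rates}
#'   (events/day).
#' @param knots spline knots: boundary and interior (length 3 for df = 2).
#' @param visit_interval days between scheduled draws (quarterly default).
#' @param postsurgical_offset day of the extra postsurgical draw.
#' @param admin_censor administrative censoring day.
#' @param dropout_prob per-visit probability of leaving the study (MAR).
#' @param prob_tp53,prob_t4,prob_act covariate and treatment prevalences.
#' @param act_start_range,act_duration adjuvant chemotherapy timing (days).
#' @param seed integer seed.
#' @return object of class \code{sim_params}.
#' @export
simulation_params <- function(n_subjects = 300,
                              beta0 = -1.5,
                              beta = c(2.2, 2.2),
                              D = matrix(c(6.25, 1.5, 1.5, 9), 2, 2),
                              sigma = 0.4,
                              gamma1 = log(3.3),
                              gamma2 = log(2.7),
                              alpha1 = 0.8,
                              alpha2 = 0,
                              alpha3 = 0.02,
                              baseline = list(
                                cuts = c(0, 135, 270, 450, 600),
                                rates = 1e-4 * c(0.5, 1, 0.8, 0.5, 0.3)),
                              knots = c(0, 365, 730),
                              visit_interval = 3 * DAYS_PER_MONTH,
                              postsurgical_offset = 14,
                              admin_censor = 730,
                              dropout_prob = 0.05,
                              prob_tp53 = 0.7,
                              prob_t4 = 0.08,
                              prob_act = 0.65,
                              act_start_range = c(25, 45),
                              act_duration = 73,
                              seed = 1L) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8) || any(eigen(D, symmetric = TRUE,
                                                only.values = TRUE)$values < -1e-10))
    stop("D must be a symmetric positive semi-definite matrix")
  if (sigma < 0) stop("sigma must be >= 0")
  if (visit_interval <= 0) stop("visit_interval must be > 0")
  if (any(baseline$rates < 0)) stop("baseline rates must be >= 0")
  stopifnot(length(baseline$cuts) == length(baseline$rates),
            baseline$cuts[1] == 0, length(beta) == 2, length(knots) == 3)
  structure(as.list(environment()), class = "sim_params")
}

## trajectory pieces for one subject: eta(t), eta'(t), int_0^t eta
.traj_fns <- function(beta0, a, basis) {
  list(
    eta = function(t) beta0 + drop(suppressWarnings(ncs_eval(basis, t)) %*% a),
    deta = function(t) drop(suppressWarnings(ncs_eval(basis, t, deriv = 1)) %*% a),
    ieta = function(t) beta0 * t + drop(ncs_integral(basis, t) %*% a))
}

## cumulative hazard for one subject, Gauss-Legendre per baseline interval;
## the cumulative hazard at each interval start is cached so repeated calls
## during bisection integrate only the partial interval
.subject_cumhaz_fn <- function(lp, beta0, a, alphas, baseline, basis,
                               gl = gauss_legendre(15), t_max = Inf) {
  tf <- .traj_fns(beta0, a, basis)
  cuts <- baseline$cuts; rates <- baseline$rates
  upper <- c(cuts[-1], t_max)
  seg_H <- function(a0, b0, rate) {
    if (b0 <= a0 || rate == 0) return(0)
    g <- gl_rescale(gl, a0, b0)
    s <- g$nodes
    loghaz <- log(rate) + alphas[1] * tf$eta(s) + alphas[2] * tf$deta(s) +
      alphas[3] * tf$ieta(s)
    sum(g$weights * exp(pmin(loghaz + lp, 700)))
  }
  Hcut <- numeric(length(cuts))  # H at each interval start
  for (j in seq_along(cuts)[-1])
    Hcut[j] <- Hcut[j - 1] + seg_H(cuts[j - 1], cuts[j], rates[j - 1])
  function(t) {
    j <- findInterval(t, cuts)
    if (j < 1) return(0)
    Hcut[j] + seg_H(cuts[j], min(t, upper[j]), rates[j])
  }
}

## invert H(T) = target by bisection to 1e-8 days
.invert_cumhaz <- function(Hfn, target, t_cap) {
  if (Hfn(t_cap) < target) return(Inf)
  lo <- 0; hi <- t_cap
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (Hfn(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a joint longitudinal--survival cohort
#'
#' Draws subject-specific log ctDNA trajectories from the spline mixed
#' model, recurrence times by inverting the cumulative hazard linked to the
#' trajectory, quarterly measurements with Gaussian error before the
#' observed (possibly censored) time, and clinical covariates. The Gaussian
#' working scale may dip below zero; materialised VAFs are floored at zero
#' (a zero VAF is an at-detection-limit observation), and \code{positive}
#' means a strictly positive measured level.
#'
#' @param params a [simulation_params()] object.
#' @return object of class \code{synthetic_cohort}: list with
#'   \code{subjects}, \code{series}, \code{truth} data.frames, plus the
#'   \code{params} and fitted-scale \code{basis}.
#' @export
simulate_joint_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  n <- p$n_subjects
  basis <- ncs_basis(knots = p$knots[2], boundary = p$knots[c(1, 3)])
  L <- chol(p$D + diag(1e-12, 2))
  b <- matrix(rnorm(2 * n), n, 2) %*% L
  tp53 <- rbinom(n, 1, p$prob_tp53)
  t4 <- rbinom(n, 1, p$prob_t4)
  act <- rbinom(n, 1, p$prob_act)
  act_start <- ifelse(act == 1,
                      round(runif(n, p$act_start_range[1],
                                  p$act_start_range[2])), NA)
  act_end <- ifelse(act == 1, act_start + p$act_duration, NA)
  t_cap <- p$knots[3] + 0.5 * (p$knots[3] - p$knots[1])  # safe extrapolation
  alphas <- c(p$alpha1, p$alpha2, p$alpha3)
  u <- runif(n)
  true_event <- numeric(n)
  for (i in seq_len(n)) {
    lp <- p$gamma1 * tp53[i] + p$gamma2 * t4[i]
    Hfn <- .subject_cumhaz_fn(lp, p$beta0, p$beta + b[i, ], alphas,
                              p$baseline, basis)
    true_event[i] <- .invert_cumhaz(Hfn, -log(u[i]), t_cap)
  }
  ## visit schedule: surgery day 0, postsurgical draw, then quarterly
  sched <- sort(unique(c(0, p$postsurgical_offset,
                         seq(p$visit_interval, p$admin_censor,
                             by = p$visit_interval))))
  drop_day <- rep(Inf, n)
  for (i in seq_len(n)) {
    later <- sched[sched > 0]
    gone <- runif(length(later)) < p$dropout_prob
    if (any(gone)) drop_day[i] <- later[which(gone)[1]]
  }
  rfs <- pmin(true_event, p$admin_censor, drop_day)
  event <- as.integer(true_event <= pmin(p$admin_censor, drop_day))
  subjects <- data.frame(
    patient = sprintf("P%03d", seq_len(n)),
    tp53_mut = tp53 == 1, t4_stage = t4 == 1,
    stage = ifelse(t4 == 1, "III", sample(c("II", "III"), n, TRUE)),
    act_received = act == 1, act_start_day = act_start,
    act_end_day = act_end, rfs_day = rfs, event = event)
  series <- do.call(rbind, lapply(seq_len(n), function(i) {
    tt <- sched[sched < rfs[i]]
    if (length(tt) == 0) tt <- 0
    eta <- p$beta0 + drop(ncs_eval(basis, tt) %*% (p$beta + b[i, ]))
    y <- eta + rnorm(length(tt), 0, p$sigma)
    data.frame(patient = subjects$patient[i], day = tt, log_ctdna = y,
               mean_vaf = ifelse(y > 0, mean_vaf_from_level(y), 0),
               positive = y > 0)
  }))
  truth <- data.frame(patient = subjects$patient, b1 = b[, 1], b2 = b[, 2],
                      true_event_day = true_event, eta0 = p$beta0)
  structure(list(subjects = subjects, series = series, truth = truth,
                 params = p, basis = basis),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic cohort:", nrow(x$subjects), "subjects,",
      nrow(x$series), "measurements,",
      sum(x$subjects$event), "events\n")
  invisible(x)
}

#' Simulate UMI read families for the MRD caller
#'
#' Per locus, \code{depth} original molecules are drawn; mutant molecules
#' follow Binomial(depth, truth_vaf). Each molecule emits a single-strand
#' family with UMI pair (A, B) and, with probability \code{duplex_prob}, the
#' complementary-strand family with the transposed pair (B, A). Per-read
#' per-base substitution errors are injected uniformly over the three
#' alternative bases.
#'
#' @param truth_vaf vector of true variant allele fractions, one per locus.
#' @param depth consensus families (molecules) per locus.
#' @param reads_per_family list: \code{dist} = "shifted_poisson" (1 +
#'   Poisson(mean - 1)) or "fixed"; \code{mean}.
#' @param error_rate per-read per-base substitution probability (< 0.01).
#' @param duplex_prob probability that both strands of a molecule are
#'   recovered.
#' @param positions,contig locus coordinates (defaults: 1..n on "chr1").
#' @param ref,alt reference and true alternate base per locus.
#' @param seed integer seed (NULL to use the current RNG stream).
#' @return list of class \code{read_family_set}: \code{reads} (long table:
#'   contig, pos, umiA, umiB, orientation, read_idx, allele),
#'   \code{ref_alleles}, and the per-locus \code{truth}.
#' @export
simulate_read_families <- function(truth_vaf, depth,
                                   reads_per_family = list(
                                     dist = "shifted_poisson", mean = 3),
                                   error_rate = 1e-3,
                                   duplex_prob = 0.5,
                                   positions = NULL, contig = "chr1",
                                   ref = "A", alt = "T", seed = NULL) {
  stopifnot(all(truth_vaf >= 0), all(truth_vaf <= 1), error_rate < 0.01,
            error_rate >= 0, depth >= 1)
  if (!is.null(seed)) set.seed(seed)
  nloc <- length(truth_vaf)
  if (is.null(positions)) positions <- seq_len(nloc)
  ref <- rep_len(ref, nloc); alt <- rep_len(alt, nloc)
  bases <- c("A", "C", "G", "T")
  ## molecules
  n_mut <- rbinom(nloc, depth, truth_vaf)
  mol <- data.table(
    locus = rep(seq_len(nloc), each = depth),
    mol = rep(seq_len(depth), nloc))
  mol[, true_allele := ifelse(mol <= n_mut[locus], alt[locus], ref[locus])]
  mol[, umi_a := paste0("a", locus, "_", mol)]
  mol[, umi_b := paste0("b", locus, "_", mol)]
  ## families: AB always, BA with prob duplex_prob
  dup <- runif(nrow(mol)) < duplex_prob
  fam <- rbind(
    mol[, .(locus, mol, true_allele, umiA = umi_a, umiB = umi_b,
            orientation = "AB")],
    mol[dup, .(locus, mol, true_allele, umiA = umi_b, umiB = umi_a,
               orientation = "BA")])
  nf <- nrow(fam)
  fam[, n_reads := if (reads_per_family$dist == "fixed")
        rep(as.integer(reads_per_family$mean), nf)
      else 1L + rpois(nf, reads_per_family$mean - 1)]
  reads <- fam[rep(seq_len(nf), fam$n_reads)]
  reads[, read_idx := seq_len(.N), by = .(locus, umiA, umiB, orientation)]
  ## per-read substitution errors
  err <- runif(nrow(reads)) < error_rate
  if (any(err)) {
    cur <- reads$true_allele[err]
    sub <- vapply(cur, function(bb) sample(setdiff(bases, bb), 1), "")
    reads[, allele := true_allele]
    reads[err, allele := sub]
  } else reads[, allele := true_allele]
  out <- reads[, .(contig = contig, pos = positions[locus], umiA, umiB,
                   orientation, read_idx, allele)]
  setDF(out)
  structure(list(
    reads = out,
    ref_alleles = data.frame(contig = contig, pos = positions, ref = ref),
    truth = data.frame(contig = contig, pos = positions, ref = ref,
                       alt = alt, truth_vaf = truth_vaf,
                       n_mutant_molecules = n_mut)),
    class = "read_family_set")
}

#' Deterministic eight-subject fixture cohort
#'
#' Hand-specified, RNG-free cohort used across the unit tests: two calls
#' always return identical output. Contains events, censored subjects,
#' TP53-mutant and T4 subjects, ACT exposure, and longitudinal series with
#' rising, flat and undetectable trajectories.
#'
#' @return a \code{synthetic_cohort} (with \code{truth = NULL}).
#' @export
cohort_fixture_small <- function() {
  subjects <- data.frame(
    patient = sprintf("F%02d", 1:8),
    tp53_mut = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    t4_stage = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stage = c("III", "II", "II", "III", "II", "III", "II", "II"),
    act_received = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    act_start_day = c(35, 40, NA, 30, 38, NA, 42, NA),
    act_end_day = c(108, 113, NA, 103, 111, NA, 115, NA),
    rfs_day = c(120, 200, 250, 320, 400, 500, 600, 730),
    event = c(1L, 1L, 0L, 1L, 0L, 1L, 0L, 0L))
  mk <- function(pat, day, lvl) data.frame(patient = pat, day = day,
                                           log_ctdna = lvl)
  series <- rbind(
    mk("F01", c(0, 14, 91),        c(5.2, 4.1, 6.0)),
    mk("F02", c(0, 14, 91, 183),   c(3.0, 1.5, 2.8, 4.6)),
    mk("F03", c(0, 14, 91, 183),   c(1.2, 0.0, 0.0, 0.0)),
    mk("F04", c(0, 14, 91, 183, 274), c(4.4, 0.0, 1.1, 3.2, 5.5)),
    mk("F05", c(0, 14, 91, 183, 274, 365), c(0.0, 0.0, 0.0, 0.0, 0.0, 0.0)),
    mk("F06", c(0, 14, 91, 183, 274, 365, 457), c(2.1, 0.8, 0.0, 1.4, 2.9, 4.8, 7.1)),
    mk("F07", c(0, 14, 91, 183, 274, 365, 457, 548), rep(0, 8)),
    mk("F08", c(0, 14, 91, 183, 274, 365, 457, 548, 639), c(1.8, rep(0, 8))))
  series$mean_vaf <- ifelse(series$log_ctdna > 0,
                            mean_vaf_from_level(series$log_ctdna), 0)
  series$positive <- series$log_ctdna > 0
  basis <- ncs_basis(knots = 365, boundary = c(0, 730))
  structure(list(subjects = subjects, series = series, truth = NULL,
                 params = NULL, basis = basis),
            class = "synthetic_cohort")
}
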