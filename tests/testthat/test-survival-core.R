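test_that("Kaplan-Meier handles degenerate and closed-form cases", {
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  # all censored: S = 1 everywhere
  km <- km_estimate(c(5, 10, 15), c(0, 0, 0))
  expect_equal(km$surv, rep(1, 3))
  # all events at distinct times: product-limit closed form
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # mixed toy set, hand-computed: times 1(e), 2(c), 3(e), 4(e)
  # S(1) = 3/4; S(3) = 3/4 * 1/2 = 3/8; S(4) = 0
  km <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(km_surv_at(km, c(1, 2.5, 3, 4)), c(3/4, 3/4, 3/8, 0))
})

test_that("Kaplan-Meier matches the survival package incl. Greenwood SE", {
  skip_if_not_installed("survival")
  set.seed(42)
  tt <- rexp(40, 0.1); ev <- rbinom(40, 1, 0.6)
  km <- km_estimate(tt, ev)
  ref <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  expect_equal(km_surv_at(km, sort(tt)), summary(ref, times = sort(tt))$surv,
               tolerance = 1e-12)
  sm <- summary(ref)
  keep <- sm$surv > 0   # the reference reports NaN once S hits 0
  idx <- match(sm$time[keep], km$time)
  expect_equal(km$se[idx], sm$std.err[keep], tolerance = 1e-10)
})

test_that("log-rank: symmetry, oracle match and Cox score equivalence", {
  # two identical groups: statistic ~ 0
  tt <- c(2, 4, 6, 8, 10); ev <- c(1, 1, 0, 1, 0)
  lr <- logrank_test(c(tt, tt), c(ev, ev), rep(1:2, each = 5))
  expect_lt(lr$statistic, 1e-10)
  expect_equal(lr$p_value, 1, tolerance = 1e-6)
  # toy two-group data vs the survival package (no ties)
  skip_if_not_installed("survival")
  set.seed(7)
  tt <- c(1.1, 2.3, 3.7, 4.1, 5.9, 6.2, 7.8, 9.4, 10.6, 12.3)
  ev <- c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1)
  gr <- rep(1:2, 5)
  lr <- logrank_test(tt, ev, gr)
  ref <- survival::survdiff(survival::Surv(tt, ev) ~ gr)
  expect_equal(lr$statistic, ref$chisq, tolerance = 1e-10)
  # equals the Cox partial-likelihood score test for the group indicator
  cx <- cox_fit(cbind(g = as.numeric(gr == 2)), tt, ev)
  expect_equal(lr$statistic, cx$score_stat, tolerance = 1e-8)
})

test_that("cox_fit maximises the partial likelihood (brute-force oracle)", {
  # 6 subjects, one binary covariate, no ties
  tt <- c(1, 3, 4, 6, 8, 9)
  ev <- c(1, 1, 0, 1, 1, 0)
  x <- c(1, 0, 1, 1, 0, 0)
  fit <- cox_fit(cbind(x = x), tt, ev)
  # oracle: direct partial likelihood, optimised on a fine grid
  pl <- function(b) {
    s <- 0
    for (i in which(ev == 1))
      s <- s + b * x[i] - log(sum(exp(b * x[tt >= tt[i]])))
    s
  }
  bgrid <- seq(-4, 4, by = 1e-4)
  b_star <- bgrid[which.max(vapply(bgrid, pl, 0))]
  expect_equal(unname(fit$coef), b_star, tolerance = 1e-3)
  expect_gte(pl(unname(fit$coef)), pl(b_star) - 1e-8)
})

test_that("cox_fit agrees with survival::coxph for Efron and Breslow ties", {
  skip_if_not_installed("survival")
  set.seed(11)
  n <- 60
  x <- cbind(a = rbinom(n, 1, 0.4), b = rnorm(n))
  tt <- round(rexp(n, 0.1) * exp(-0.6 * x[, 1])) + 1  # induces ties
  ev <- rbinom(n, 1, 0.7)
  for (ties in c("efron", "breslow")) {
    fit <- cox_fit(x, tt, ev, ties = ties)
    ref <- survival::coxph(survival::Surv(tt, ev) ~ a + b,
                           data = data.frame(x), ties = ties)
    expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
  }
})

test_that("cox_fit invariances and error paths", {
  set.seed(3)
  n <- 50
  g <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.05 * exp(g)); ev <- rbinom(n, 1, 0.8)
  f1 <- cox_fit(cbind(g = g), tt, ev)
  f2 <- cox_fit(cbind(g = 1 - g), tt, ev)
  expect_equal(unname(f1$coef), -unname(f2$coef), tolerance = 1e-7)
  # likelihood invariant to covariate centering
  f3 <- cox_fit(cbind(g = g - 10), tt, ev)
  expect_equal(f1$loglik, f3$loglik, tolerance = 1e-9)
  expect_error(cox_fit(cbind(rep(1, n)), tt, ev), "constant")
  expect_error(cox_fit(cbind(g = g[1:3]), tt[1:3], c(0, 0, 0)),
               "fewer events")
})

test_that("breslow baseline reproduces Nelson-Aalen with null covariate", {
  skip_if_not_installed("survival")
  set.seed(5)
  tt <- rexp(30, 0.1); ev <- rbinom(30, 1, 0.7)
  x <- rnorm(30)
  fit <- cox_fit(cbind(x = x), tt, ev)
  H0 <- breslow_cumhaz(fit)
  ref <- survival::basehaz(survival::coxph(survival::Surv(tt, ev) ~ x),
                           centered = FALSE)
  expect_equal(H0(ref$time), ref$hazard, tolerance = 1e-8)
})

test_that("signed-rank test: exact enumeration oracle and edge cases", {
  # degenerate: all zeros
  expect_equal(signed_rank_test(rep(0, 5))$p_value, 1)
  # n = 6: exact p equals enumeration over all 2^6 sign assignments
  x <- c(3.2, -1.1, 4.8, 0.7, -2.4, 5.1)
  res <- signed_rank_test(x)
  r <- rank(abs(x))
  W_all <- apply(expand.grid(rep(list(0:1), 6)), 1,
                 function(s) sum(r[s == 1]))
  center <- sum(r) / 2
  w_obs <- sum(r[x > 0])
  p_exact <- mean(abs(W_all - center) >= abs(w_obs - center) - 1e-12)
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
  # matches wilcox.test exact p on tie-free data
  expect_equal(res$p_value,
               suppressWarnings(wilcox.test(x, exact = TRUE)$p.value),
               tolerance = 1e-10)
  # ties handled exactly by the DP (enumeration with average ranks)
  xt <- c(2, 2, -2, 5, 7, -5)
  rt <- rank(abs(xt))
  W_all <- apply(expand.grid(rep(list(0:1), 6)), 1,
                 function(s) sum(rt[s == 1]))
  w_obs <- sum(rt[xt > 0])
  center <- sum(rt) / 2
  p_exact <- mean(abs(W_all - center) >= abs(w_obs - center) - 1e-12)
  expect_equal(signed_rank_test(xt)$p_value, p_exact, tolerance = 1e-12)
  # n > 25: normal approximation with continuity correction, as wilcox.test
  set.seed(8)
  xl <- rnorm(30, 0.3)
  expect_equal(signed_rank_test(xl)$p_value,
               suppressWarnings(wilcox.test(xl, exact = FALSE,
                                            correct = TRUE)$p.value),
               tolerance = 1e-10)
})

test_that("lead-time analysis reports median lead and signed-rank p", {
  # patient positive 189 days before imaging-confirmed recurrence
  lt <- lead_time_analysis(c(100), c(289))
  expect_equal(lt$median_lead, 189)
  # all leads zero: median 0, p = 1
  lt0 <- lead_time_analysis(c(10, 20, 30), c(10, 20, 30))
  expect_equal(lt0$median_lead, 0)
  expect_equal(lt0$p_value, 1)
  # typical case: positive precedes recurrence
  set.seed(2)
  pos <- c(100, 150, 80, 200, 90, 120, 60, 210)
  rec <- pos + c(88, 40, 120, 30, 95, 60, 150, 10)
  lt <- lead_time_analysis(pos, rec)
  expect_equal(lt$median_lead, median(rec - pos))
  expect_lt(lt$p_value, 0.01)
  expect_error(lead_time_analysis(NA_real_, NA_real_), "no complete pairs")
})

test_that("landmark status classification follows the window rules", {
  subjects <- data.frame(
    patient = c("A", "B", "C", "D"),
    act_received = c(TRUE, FALSE, TRUE, TRUE),
    act_start_day = c(40, NA, 20, 45),
    act_end_day = c(113, NA, 93, 118),
    rfs_day = c(700, 700, 400, 300),
    event = c(0L, 0L, 1L, 1L))
  plasma <- data.frame(
    patient = c("A", "A", "B", "B", "C", "D", "D"),
    day = c(25, 200, 45, 200, 25, 14, 250),
    positive = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
  st <- classify_landmark_status(subjects, plasma)
  # idempotent and order-invariant over samples
  st_perm <- classify_landmark_status(subjects, plasma[sample(7), ])
  expect_equal(st, st_perm, ignore_attr = TRUE)
  rownames(st) <- st$patient
  # A: positive sample day 25, ACT starts day 40 -> postsurgical positive
  expect_true(st["A", "postsurgical"])
  # B: only sample at day 45 -> postsurgical window missed -> NA
  expect_true(is.na(st["B", "postsurgical"]))
  # B: positive later -> longitudinal positive
  expect_true(st["B", "longitudinal"])
  # C: sample at day 25 is after ACT start (day 20) -> excluded -> NA
  expect_true(is.na(st["C", "postsurgical"]))
  # D: negative postsurgical but positive at day 250 -> longitudinal positive
  expect_false(st["D", "postsurgical"])
  expect_true(st["D", "longitudinal"])
  # post-ACT window: A has sample at day 200 in (113, 234.76] -> negative
  expect_false(st["A", "post_act"])
  # samples after the recurrence date are excluded with a warning
  plasma2 <- rbind(plasma, data.frame(patient = "D", day = 320,
                                      positive = TRUE))
  expect_warning(classify_landmark_status(subjects, plasma2),
                 "after the recurrence")
})
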