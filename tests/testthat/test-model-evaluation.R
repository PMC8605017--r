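test_that("time-dependent AUROC: exchangeability, perfect ranking, oracle", {
  t0 <- 100; u <- 400
  time <- c(150, 200, 250, 300, 500, 600, 700, 800)
  event <- c(1, 1, 1, 1, 0, 0, 0, 0)     # no censoring inside (t, u]
  # identical predictions: 0.5 by tie convention
  expect_equal(time_dependent_auroc(rep(0.4, 8), time, event, t0, u), 0.5)
  # perfectly separating scores
  risk <- c(0.9, 0.8, 0.85, 0.95, 0.1, 0.2, 0.15, 0.05)
  expect_equal(time_dependent_auroc(risk, time, event, t0, u), 1.0)
  # fully observed 8-subject toy vs brute-force pair enumeration
  set.seed(9)
  risk <- runif(8)
  auc <- time_dependent_auroc(risk, time, event, t0, u)
  num <- den <- 0
  for (i in which(time <= u & event == 1)) for (j in which(time > u)) {
    num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    den <- den + 1
  }
  expect_equal(auc, num / den)
  # invariant under strictly monotone transform of the scores
  expect_equal(time_dependent_auroc(qlogis(risk / 2 + 0.25), time, event,
                                    t0, u), auc)
})

test_that("AUROC handles censored-in-window subjects by fractional weights", {
  t0 <- 0; u <- 10
  time <- c(5, 8, 20, 30)      # subject 2 censored inside the window
  event <- c(1, 0, 0, 0)
  risk <- c(0.9, 0.6, 0.3, 0.2)
  nu <- c(NA, 0.25, NA, NA)    # model-based P(event by u | alive at 8)
  auc <- time_dependent_auroc(risk, time, event, t0, u,
                              event_prob_at_censor = nu)
  # hand computation: case weights w = (1, .25, 0, 0), controls 1 - w
  w <- c(1, 0.25, 0, 0); v <- 1 - w
  num <- 0; den <- 0
  for (i in 1:4) for (j in setdiff(1:4, i)) {
    num <- num + w[i] * v[j] * ((risk[i] > risk[j]) +
                                  0.5 * (risk[i] == risk[j]))
    den <- den + w[i] * v[j]
  }
  expect_equal(auc, num / den)
  # missing weights for censored-in-window subjects must error
  expect_error(time_dependent_auroc(risk, time, event, t0, u),
               "event_prob_at_censor")
  # ipcw alternative runs and stays in [0, 1]
  a2 <- time_dependent_auroc(risk, time, event, t0, u, method = "ipcw")
  expect_true(a2 >= 0 && a2 <= 1)
  # degenerate window: no cases -> NA with warning
  expect_warning(
    a3 <- time_dependent_auroc(risk[3:4], time[3:4], event[3:4], t0, u),
    "no comparable")
  expect_true(is.na(a3))
})

test_that("prediction error: closed forms and censored decomposition", {
  t0 <- 100; u <- 400
  time <- c(150, 200, 500, 600)
  event <- c(1, 1, 0, 0)
  # perfect predictions, no censoring in window
  expect_equal(prediction_error(c(0, 0, 1, 1), time, event, t0, u), 0)
  # constant pi = 0.5
  expect_equal(prediction_error(rep(0.5, 4), time, event, t0, u), 0.25)
  # constant predictor pi = observed survivor fraction: p(1-p) exactly
  p_surv <- 0.5
  expect_equal(prediction_error(rep(p_surv, 4), time, event, t0, u),
               p_surv * (1 - p_surv))
  # censored-in-window: hand-computed three-term decomposition
  time2 <- c(150, 300, 500)   # second subject censored at 300
  event2 <- c(1, 0, 0)
  pi2 <- c(0.2, 0.6, 0.9)
  pic <- c(NA, 0.7, NA)       # pi(u | c = 300)
  pe <- prediction_error(pi2, time2, event2, t0, u, pi_at_censor = pic)
  by_hand <- (0.2^2 +                         # event
                (0.7 * (1 - 0.6)^2 + 0.3 * 0.6^2) +  # censored split
                (1 - 0.9)^2) / 3              # survivor
  expect_equal(pe, by_hand)
  expect_error(prediction_error(pi2, time2, event2, t0, u), "pi_at_censor")
})

test_that("repeated k-fold CV: defaults, determinism, partition property", {
  # paper-anchored defaults
  expect_equal(eval(formals(repeated_kfold_cv)$k), 5)
  expect_equal(eval(formals(repeated_kfold_cv)$repeats), 20)
  # a cheap spec so the harness itself is exercised quickly
  dummy <- list(name = "dummy",
                fit = function(train, t) NULL,
                predict = function(model, test, t, u) {
                  risk <- test$subjects[test$subjects$rfs_day > t, ]
                  data.frame(patient = risk$patient,
                             pi = plogis(risk$rfs_day / 400),
                             pi_c = 0.5)
                })
  p <- simulation_params(n_subjects = 60, seed = 17)
  ch <- simulate_joint_cohort(p)
  cv1 <- repeated_kfold_cv(ch, list(dummy = dummy), k = 4, repeats = 3,
                           seed = 7)
  cv2 <- repeated_kfold_cv(ch, list(dummy = dummy), k = 4, repeats = 3,
                           seed = 7)
  expect_equal(cv1, cv2)
  # each subject appears in exactly one test fold per repeat
  folds <- attr(cv1, "folds")
  expect_equal(length(folds), 3)
  for (f in folds) {
    expect_equal(length(f), 60)
    expect_true(all(f %in% 1:4))
  }
  # folds differ across repeats (they are re-drawn)
  expect_false(identical(folds[[1]], folds[[2]]))
  # output shape: 2 metrics x 2 windows x 3 repeats
  expect_equal(nrow(cv1), 12)
  expect_true(all(cv1$metric %in% c("AUROC", "PE")))
})

test_that("Hosmer-Lemeshow: perfect calibration, KM-observed, hand check", {
  # 24 subjects in two risk strata with event fractions 0.25 and 0.75 by u;
  # a dummy model predicting exactly those fractions is perfectly calibrated
  t0 <- 0; u <- 100
  subjects <- data.frame(
    patient = sprintf("S%02d", 1:24),
    tp53_mut = FALSE, t4_stage = FALSE, stage = "II",
    act_received = FALSE, act_start_day = NA, act_end_day = NA,
    rfs_day = c(rep(c(50, 200, 200, 200), 3),   # low risk: 25% events
                rep(c(40, 60, 80, 200), 3)),    # high risk: 75% events
    event = c(rep(c(1, 0, 0, 0), 3), rep(c(1, 1, 1, 0), 3)))
  # censored-after-u subjects: KM at u equals the raw fraction here
  series <- data.frame(patient = subjects$patient, day = 0,
                       log_ctdna = 0, mean_vaf = 0, positive = FALSE)
  cohort <- list(subjects = subjects, series = series,
                 basis = ncs_basis(knots = 100, boundary = c(0, 250)))
  # pi = event-FREE probability: 0.75 for the 25%-event stratum, etc.
  pred_map <- setNames(rep(c(0.75, 0.25), each = 12), subjects$patient)
  spec <- list(name = "fixed",
               fit = function(train, t) NULL,
               predict = function(model, test, t, u) {
                 ids <- test$subjects$patient[test$subjects$rfs_day > t]
                 data.frame(patient = ids, pi = pred_map[ids], pi_c = NA)
               })
  hl <- loocv_hosmer_lemeshow(cohort, spec, c(t0, u), n_groups = 2)
  expect_equal(hl$C, 0, tolerance = 1e-12)
  expect_equal(hl$p_value, 1, tolerance = 1e-12)
  expect_equal(sort(hl$table$observed), c(0.25, 0.75))
  # observed probabilities come from KM, not raw fractions: censor one
  # subject before u in the high-risk group and check the KM value is used
  subjects2 <- subjects
  subjects2$rfs_day[24] <- 70   # was 200 (censored after u); now inside
  cohort2 <- list(subjects = subjects2, series = series,
                  basis = cohort$basis)
  hl2 <- loocv_hosmer_lemeshow(cohort2, spec, c(t0, u), n_groups = 2)
  # high-risk group = patients S13..S24 (predicted 0.25 stratum holds S01-12)
  obs_high <- 1 - km_surv_at(km_estimate(subjects2$rfs_day[13:24],
                                         subjects2$event[13:24]), u)
  raw_high <- mean(subjects2$rfs_day[13:24] <= u & subjects2$event[13:24])
  expect_false(isTRUE(all.equal(obs_high, raw_high)))  # KM differs from raw
  expect_true(any(abs(hl2$table$observed - obs_high) < 1e-12))
  # hand-computed C for a 3-group table
  tab <- data.frame(n = c(10, 10, 10), expected = c(0.2, 0.5, 0.8),
                    observed = c(0.3, 0.45, 0.9))
  C_hand <- sum(tab$n * (tab$observed - tab$expected)^2 /
                  (tab$expected * (1 - tab$expected)))
  expect_equal(C_hand, 10 * (0.1^2 / 0.16 + 0.05^2 / 0.25 + 0.1^2 / 0.16))
})

test_that("paired model comparison uses the exact signed-rank test", {
  d <- expand.grid(model = c("a", "b", "c"), repeat_id = 1:6,
                   metric = "AUROC", stringsAsFactors = FALSE)
  d$t <- 100; d$u <- 200
  set.seed(3)
  d$value <- runif(nrow(d))
  cmp <- compare_prediction_models(d)
  # all three unordered pairs are present
  expect_equal(nrow(cmp), 3)
  # p equals the package signed-rank test on the paired differences
  a <- d$value[d$model == "a"][order(d$repeat_id[d$model == "a"])]
  b <- d$value[d$model == "b"][order(d$repeat_id[d$model == "b"])]
  expect_equal(cmp$p_value[cmp$model_a == "a" & cmp$model_b == "b"],
               signed_rank_test(a - b)$p_value)
  # identical distributions -> p = 1
  d2 <- d; d2$value[d2$model == "b"] <- d2$value[d2$model == "a"]
  cmp2 <- compare_prediction_models(d2)
  expect_equal(cmp2$p_value[cmp2$model_a == "a" & cmp2$model_b == "b"], 1)
  # unequal lengths error
  d3 <- d[-1, ]
  expect_error(compare_prediction_models(d3), "unequal")
})
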