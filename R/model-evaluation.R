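## Censoring-aware evaluation of dynamic predictions in a window (t, u]:
## time-dependent AUROC (pair-based, with model-based fractional weights for
## subjects censored inside the window, or IPCW), prediction error with the
## event/survivor decomposition at the censoring time, a repeated stratified
## k-fold cross-validation harness over model specs, leave-one-out
## Hosmer-Lemeshow calibration with Kaplan-Meier observed probabilities,
## and paired Wilcoxon signed-rank model comparison.

#' Time-dependent AUROC under censoring
#'
#' Pair-based estimator on the landmark risk set: a comparable pair is a
#' case (event in (t, u]) and a control (event-free at u); the AUROC is the
#' fraction of comparable pairs in which the case has the higher predicted
#' event risk (ties count one half). Subjects censored inside the window
#' contribute fractionally: with case weight equal to their model-based
#' conditional event probability (\code{event_prob_at_censor}) and control
#' weight equal to its complement. \code{method = "ipcw"} instead drops
#' censored-in-window subjects and weights pairs by inverse censoring
#' probabilities from the Kaplan-Meier censoring distribution.
#'
#' @param risk predicted event probability by u (higher = riskier).
#' @param time,event observed times and event indicators (risk set: time > t).
#' @param t,u landmark and horizon days.
#' @param event_prob_at_censor P(event by u | alive at censoring time) for
#'   subjects censored in (t, u] (NA elsewhere); required by the model
#'   method when such subjects exist.
#' @param method "model" (default) or "ipcw".
#' @return scalar AUROC (NA with a warning when no comparable pairs).
#' @export
time_dependent_auroc <- function(risk, time, event, t, u,
                                 event_prob_at_censor = NULL,
                                 method = c("model", "ipcw")) {
  method <- match.arg(method)
  stopifnot(u > t)
  keep <- time > t
  risk <- risk[keep]; time <- time[keep]; event <- as.integer(event[keep])
  if (!is.null(event_prob_at_censor))
    event_prob_at_censor <- event_prob_at_censor[keep]
  n <- length(risk)
  is_case <- time <= u & event == 1
  is_ctrl <- time > u
  cens_in <- time <= u & event == 0
  if (method == "model") {
    w_case <- as.numeric(is_case)
    if (any(cens_in)) {
      if (is.null(event_prob_at_censor) ||
          any(is.na(event_prob_at_censor[cens_in])))
        stop("event_prob_at_censor required for subjects censored in (t, u]")
      w_case[cens_in] <- event_prob_at_censor[cens_in]
    }
    w_ctrl <- 1 - w_case
  } else {
    Gkm <- km_estimate(time, 1 - event)
    Gt <- function(s) km_surv_at(Gkm, s)
    w_case <- ifelse(is_case, 1 / pmax(Gt(time - 1e-9), 1e-8), 0)
    w_ctrl <- ifelse(is_ctrl, 1 / pmax(Gt(u), 1e-8), 0)
  }
  conc <- outer(risk, risk, function(a, b) (a > b) + 0.5 * (a == b))
  Wp <- outer(w_case, w_ctrl)
  diag(Wp) <- 0
  denom <- sum(Wp)
  if (denom <= 0) {
    warning("no comparable case-control pairs in the window")
    return(NA_real_)
  }
  sum(Wp * conc) / denom
}

#' Prediction error (expected Brier-type loss) under censoring
#'
#' \deqn{PE(u|t) = n(t)^{-1} \sum_{i: T_i > t} [ I(T_i > u)(1-\pi_i)^2 +
#'   \delta_i I(T_i \le u) \pi_i^2 + cens. decomposition ]}
#' where \eqn{\pi_i = \pi_i(u|t)} is the predicted event-free probability.
#' A subject censored at c inside the window splits into an event branch
#' (probability \eqn{1 - \pi_i(u|c)}, loss \eqn{\pi_i^2}) and a survivor
#' branch (probability \eqn{\pi_i(u|c)}, loss \eqn{(1-\pi_i)^2}).
#'
#' @param pi predicted event-free probabilities \eqn{\pi(u|t)}.
#' @param time,event observed data (risk set: time > t).
#' @param t,u window.
#' @param pi_at_censor \eqn{\pi_i(u|c_i)} for subjects censored in (t, u].
#' @return scalar prediction error.
#' @export
prediction_error <- function(pi, time, event, t, u, pi_at_censor = NULL) {
  stopifnot(u > t)
  keep <- time > t
  pi <- pi[keep]; time <- time[keep]; event <- as.integer(event[keep])
  if (!is.null(pi_at_censor)) pi_at_censor <- pi_at_censor[keep]
  n <- length(pi)
  if (n == 0) stop("empty risk set at the landmark")
  loss <- numeric(n)
  surv <- time > u
  ev <- time <= u & event == 1
  cens <- time <= u & event == 0
  loss[surv] <- (1 - pi[surv])^2
  loss[ev] <- pi[ev]^2
  if (any(cens)) {
    if (is.null(pi_at_censor) || any(is.na(pi_at_censor[cens])))
      stop("pi_at_censor required for subjects censored in (t, u]")
    pc <- pi_at_censor[cens]
    loss[cens] <- pc * (1 - pi[cens])^2 + (1 - pc) * pi[cens]^2
  }
  mean(loss)
}

## ---- model specs for the CV harness -------------------------------------

#' Joint-model spec for cross-validation
#'
#' @param association,engine,gh_nodes,gl_nodes,control passed to
#'   [fit_joint_model()].
#' @return a model spec (list with \code{name}, \code{fit(train, t)},
#'   \code{predict(model, test, t, u)} returning \code{patient}, \code{pi}
#'   and \code{pi_c} = \eqn{\pi(u|c)} for censored-in-window subjects).
#' @export
jm_model_spec <- function(association = "value+auc", engine = "map_ml",
                          gh_nodes = 9, gl_nodes = 7,
                          control = list(adapt_passes = 1, best_effort = TRUE,
                                         maxit = 250)) {
  list(
    name = paste0("joint[", association, "]"),
    fit = function(train, t) {
      fit_joint_model(train, association = association, engine = engine,
                      basis = train$basis, gh_nodes = gh_nodes,
                      gl_nodes = gl_nodes, control = control)
    },
    predict = function(model, test, t, u) {
      risk <- test$subjects[test$subjects$rfs_day > t, , drop = FALSE]
      out <- lapply(seq_len(nrow(risk)), function(i) {
        s <- risk[i, ]
        ser <- test$series[test$series$patient == s$patient, , drop = FALSE]
        h_t <- subject_history(ser$day[ser$day <= t],
                               ser$log_ctdna[ser$day <= t],
                               s$tp53_mut, s$t4_stage, s$patient)
        pi <- .jm_pi_quad(model, h_t, t, u)
        pi_c <- NA_real_
        if (s$rfs_day <= u && s$event == 0) {
          h_c <- subject_history(ser$day, ser$log_ctdna, s$tp53_mut,
                                 s$t4_stage, s$patient)
          pi_c <- .jm_pi_quad(model, h_c, s$rfs_day, u)
        }
        data.frame(patient = s$patient, pi = pi, pi_c = pi_c)
      })
      do.call(rbind, out)
    })
}

## shared predict for the two Cox comparators
.cox_spec_predict <- function(model, test, t, u, status) {
  risk <- test$subjects[test$subjects$rfs_day > t, , drop = FALSE]
  risk <- merge(risk, status, by = "patient")
  risk <- risk[!is.na(risk$positive), , drop = FALSE]
  if (nrow(risk) == 0) return(data.frame())
  xall <- cbind(ctdna_pos = as.numeric(risk$positive),
                tp53 = as.numeric(risk$tp53_mut),
                t4 = as.numeric(risk$t4_stage))
  x <- xall[, model$covariates, drop = FALSE]
  pi <- .cox_cond_surv(model$fit, model$H0, x, t, u)
  pi_c <- rep(NA_real_, nrow(risk))
  cw <- risk$rfs_day <= u & risk$event == 0
  if (any(cw))
    pi_c[cw] <- vapply(which(cw), function(i)
      .cox_cond_surv(model$fit, model$H0, x[i, , drop = FALSE],
                     risk$rfs_day[i], u), 0)
  data.frame(patient = risk$patient, pi = pi, pi_c = pi_c)
}

#' Landmark Cox spec for cross-validation
#' @return a model spec (see [jm_model_spec()]).
#' @export
landmark_cox_spec <- function() {
  list(
    name = "landmark_cox",
    fit = function(train, t) {
      st <- ctdna_status_at(train$series, train$subjects, t)
      landmark_cox_predict(train$subjects, st, landmark = t,
                           horizons = numeric(0))
    },
    predict = function(model, test, t, u) {
      st <- ctdna_status_at(test$series, test$subjects, t)
      .cox_spec_predict(model, test, t, u, st)
    })
}

#' Static (postsurgical status) Cox spec for cross-validation
#' @return a model spec (see [jm_model_spec()]).
#' @export
static_cox_spec <- function() {
  ps_status <- function(cohort) {
    cls <- classify_landmark_status(cohort$subjects,
                                    cohort$series[, c("patient", "day",
                                                      "positive")])
    data.frame(patient = cls$patient, positive = cls$postsurgical)
  }
  list(
    name = "static_cox",
    fit = function(train, t) {
      st <- ps_status(train)
      static_cox_predict(train$subjects, st, landmark = t,
                         horizons = numeric(0))
    },
    predict = function(model, test, t, u) {
      .cox_spec_predict(model, test, t, u, ps_status(test))
    })
}

.subset_cohort <- function(cohort, patients) {
  list(subjects = cohort$subjects[cohort$subjects$patient %in% patients, ,
                                  drop = FALSE],
       series = cohort$series[cohort$series$patient %in% patients, ,
                              drop = FALSE],
       basis = cohort$basis)
}

#' Repeated stratified k-fold cross-validation of dynamic predictors
#'
#' Per repeat: a random k-fold split stratified by event status; each model
#' spec is fitted on the training folds and predicts the test fold; test
#' predictions are pooled per repeat and the time-dependent AUROC and
#' prediction error are computed per evaluation window. Splits with a
#' zero-event training fold are redrawn (logged).
#'
#' @param data cohort (\code{synthetic_cohort} or subjects/series list).
#' @param specs named list of model specs ([jm_model_spec()],
#'   [landmark_cox_spec()], [static_cox_spec()]).
#' @param k folds (default 5).
#' @param repeats repeats (default 20).
#' @param windows list of c(t, u) day pairs; default landmark 8 months,
#'   horizons 12 and 15 months.
#' @param seed integer seed (drives fold assignment).
#' @return data.frame: \code{model}, \code{t}, \code{u}, \code{metric}
#'   ("AUROC"/"PE"), \code{repeat_id}, \code{value}; attribute "seed".
#' @export
repeated_kfold_cv <- function(data, specs, k = 5, repeats = 20,
                              windows = NULL, seed = 1L) {
  stopifnot(k >= 2, length(specs) >= 1, !is.null(names(specs)))
  d <- .as_cohort_data(data)
  d$basis <- d$basis %||% ncs_basis(d$series$day)
  if (is.null(windows))
    windows <- lapply(months_to_days(c(12, 15)),
                      function(u) c(months_to_days(8), u))
  set.seed(seed)
  subj <- d$subjects
  n <- nrow(subj)
  res <- list()
  fold_log <- list()
  for (r in seq_len(repeats)) {
    ## stratified fold assignment; redraw if a training fold has no events
    for (try_i in seq_len(20)) {
      fold <- integer(n)
      for (g in unique(subj$event)) {
        ii <- which(subj$event == g)
        fold[ii] <- sample(rep_len(seq_len(k), length(ii)))
      }
      ok <- all(vapply(seq_len(k), function(f)
        sum(subj$event[fold != f]) > 0 && sum(fold == f) > 0, TRUE))
      if (ok) break
      message("repeat ", r, ": fold with zero events, redrawing split")
    }
    fold_log[[r]] <- setNames(fold, subj$patient)
    preds <- list()  # preds[[spec]][[window]] pooled over folds
    for (f in seq_len(k)) {
      train <- .subset_cohort(d, subj$patient[fold != f])
      test <- .subset_cohort(d, subj$patient[fold == f])
      for (s in names(specs)) {
        fits <- list()  # one fit per landmark, shared across windows
        for (wi in seq_along(windows)) {
          t0 <- windows[[wi]][1]; u <- windows[[wi]][2]
          key <- paste(s, wi)
          tkey <- as.character(t0)
          if (is.null(fits[[tkey]]))
            fits[[tkey]] <- specs[[s]]$fit(train, t0)
          p <- specs[[s]]$predict(fits[[tkey]], test, t0, u)
          preds[[key]] <- rbind(preds[[key]], p)
        }
      }
    }
    for (s in names(specs)) {
      for (wi in seq_along(windows)) {
        t0 <- windows[[wi]][1]; u <- windows[[wi]][2]
        p <- merge(preds[[paste(s, wi)]], subj, by = "patient")
        auc <- time_dependent_auroc(1 - p$pi, p$rfs_day, p$event, t0, u,
                                    event_prob_at_censor = 1 - p$pi_c)
        pe <- prediction_error(p$pi, p$rfs_day, p$event, t0, u,
                               pi_at_censor = p$pi_c)
        res[[length(res) + 1]] <- data.frame(
          model = s, t = t0, u = u,
          metric = c("AUROC", "PE"), repeat_id = r, value = c(auc, pe))
      }
    }
  }
  out <- do.call(rbind, res)
  attr(out, "seed") <- seed
  attr(out, "folds") <- fold_log
  out
}

#' Leave-one-out Hosmer-Lemeshow calibration
#'
#' Leave-one-out predictions of the event probability in (t, u] for the
#' landmark risk set, grouped into near-equal groups by predicted risk;
#' the observed event probability per group is 1 minus the within-group
#' Kaplan-Meier survival at u (conditioned at t). Groups whose KM is
#' undefined at u are merged with their neighbor (logged), reducing the
#' degrees of freedom.
#'
#' @param data cohort.
#' @param spec a model spec.
#' @param window c(t, u) in days.
#' @param n_groups groups (default 5).
#' @return list: \code{C} statistic, \code{df}, \code{p_value},
#'   \code{table} (group, n, expected, observed).
#' @export
loocv_hosmer_lemeshow <- function(data, spec, window, n_groups = 5) {
  stopifnot(n_groups >= 2)
  d <- .as_cohort_data(data)
  d$basis <- d$basis %||% ncs_basis(d$series$day)
  t0 <- window[1]; u <- window[2]
  risk_ids <- d$subjects$patient[d$subjects$rfs_day > t0]
  preds <- list()
  for (pt in risk_ids) {
    train <- .subset_cohort(d, setdiff(d$subjects$patient, pt))
    test <- .subset_cohort(d, pt)
    model <- try(spec$fit(train, t0), silent = TRUE)
    if (inherits(model, "try-error")) next
    p <- spec$predict(model, test, t0, u)
    if (nrow(p) > 0) preds[[pt]] <- p
  }
  p <- do.call(rbind, preds)
  p <- merge(p, d$subjects, by = "patient")
  p$p_event <- 1 - p$pi
  p <- p[order(p$p_event), , drop = FALSE]
  grp <- ceiling(seq_len(nrow(p)) / (nrow(p) / n_groups))
  grp <- pmin(grp, n_groups)
  ## merge groups whose KM is undefined at u (all censored before u)
  repeat {
    bad <- NULL
    for (g in sort(unique(grp))) {
      gi <- grp == g
      tt <- p$rfs_day[gi] - t0
      ee <- p$event[gi]
      if (max(tt[ee == 1], -Inf) < (u - t0) && max(tt) < (u - t0)) {
        bad <- g; break
      }
    }
    if (is.null(bad) || length(unique(grp)) <= 2) break
    gs <- sort(unique(grp))
    nb <- if (bad == max(gs)) gs[which(gs == bad) - 1] else
      gs[which(gs == bad) + 1]
    message("Hosmer-Lemeshow: group ", bad,
            " KM undefined at the horizon; merged with group ", nb)
    grp[grp == bad] <- nb
  }
  tab <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    gi <- grp == g
    kmg <- km_estimate(p$rfs_day[gi] - t0, p$event[gi])
    obs <- 1 - km_surv_at(kmg, u - t0)
    data.frame(group = g, n = sum(gi), expected = mean(p$p_event[gi]),
               observed = obs)
  }))
  Cst <- sum(tab$n * (tab$observed - tab$expected)^2 /
               pmax(tab$expected * (1 - tab$expected), 1e-10))
  df <- nrow(tab) - 2
  list(C = Cst, df = df,
       p_value = pchisq(Cst, df = max(df, 1), lower.tail = FALSE),
       table = tab)
}

#' Paired Wilcoxon signed-rank comparison of metric distributions
#'
#' Compares models pairwise per metric and window over the paired
#' cross-validation repeats, mirroring the joint vs landmark vs static
#' comparison grid.
#'
#' @param dist output of [repeated_kfold_cv()].
#' @return data.frame: \code{model_a}, \code{model_b}, \code{t}, \code{u},
#'   \code{metric}, medians and two-sided signed-rank \code{p_value}.
#' @export
compare_prediction_models <- function(dist) {
  models <- unique(dist$model)
  wins <- unique(dist[, c("t", "u")])
  out <- list()
  for (m in unique(dist$metric)) {
    for (w in seq_len(nrow(wins))) {
      tu <- c(wins$t[w], wins$u[w])
      for (i in seq_along(models)) for (j in seq_along(models)) {
        if (j <= i) next
        a <- dist[dist$model == models[i] & dist$metric == m &
                    dist$t == tu[1] & dist$u == tu[2], ]
        b <- dist[dist$model == models[j] & dist$metric == m &
                    dist$t == tu[1] & dist$u == tu[2], ]
        a <- a[order(a$repeat_id), ]; b <- b[order(b$repeat_id), ]
        if (nrow(a) != nrow(b)) stop("unequal metric vector lengths")
        ok <- is.finite(a$value) & is.finite(b$value)  # complete pairs
        ts <- signed_rank_test(a$value[ok] - b$value[ok])
        out[[length(out) + 1]] <- data.frame(
          model_a = models[i], model_b = models[j], t = tu[1], u = tu[2],
          metric = m, median_a = median(a$value, na.rm = TRUE),
          median_b = median(b$value, na.rm = TRUE),
          n_pairs = sum(ok), p_value = ts$p_value)
      }
    }
  }
  do.call(rbind, out)
}
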