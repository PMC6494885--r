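#' Death-calling configuration
#'
#' Automated scoring of single-cell death from the morphology-channel
#' intensity trace: a cell is scored dead at the first timepoint where its
#' mean intensity falls to within `k` background standard deviations of the
#' background mean, sustained for `persistence_frames` consecutive frames —
#' the abrupt loss of the freely diffusing morphology marker that reports
#' membrane rupture. A track that simply terminates before the end of the
#' movie is also scored as a death (its object vanished), unless
#' `disappearance_is_event` is disabled, in which case it is censored at
#' last observation.
#'
#' @param drop_to_background_k multiplier on the background SD (default 3).
#' @param persistence_frames consecutive low frames required (default 2).
#' @param disappearance_is_event score early track loss as death
#'   (default `TRUE`).
#' @return A `DeathCallConfig` list.
#' @export
death_call_config <- function(drop_to_background_k = 3,
                              persistence_frames = 2,
                              disappearance_is_event = TRUE) {
  if (drop_to_background_k <= 0) stop("`drop_to_background_k` must be > 0")
  if (persistence_frames < 1) stop("`persistence_frames` must be >= 1")
  structure(list(drop_to_background_k = drop_to_background_k,
                 persistence_frames = persistence_frames,
                 disappearance_is_event = isTRUE(disappearance_is_event)),
            class = "DeathCallConfig")
}

#' Call death for one tracked cell
#'
#' @param trace data frame for one track: `timepoint_h` and `intensity_au`
#'   (morphology channel), sorted or not.
#' @param background list or vector with `mean` and `sd` of the background
#'   intensity.
#' @param config a [death_call_config()].
#' @param movie_end_h last imaged timepoint; needed to distinguish a track
#'   that ends with the movie (censored) from one that vanished early
#'   (death at the first missing frame).
#' @param frame_interval_h imaging interval, used to date a disappearance.
#' @param manual_death_h optional manually scored death time; overrides the
#'   automated call.
#' @return one-row data frame: `time_h`, `event` (1 death, 0 censored),
#'   `call` ("manual", "intensity", "disappearance" or "censored").
#' @export
call_death <- function(trace, background, config = death_call_config(),
                       movie_end_h = max(trace$timepoint_h),
                       frame_interval_h = NULL,
                       manual_death_h = NA_real_) {
  stopifnot(inherits(config, "DeathCallConfig"))
  if (is.null(background$mean) || is.null(background$sd) ||
      is.na(background$mean) || is.na(background$sd))
    stop("missing background estimate (need mean and sd)")
  if (!is.na(manual_death_h))
    return(data.frame(time_h = manual_death_h, event = 1L, call = "manual"))
  tr <- trace[order(trace$timepoint_h), ]
  cutoff <- background$mean + config$drop_to_background_k * background$sd
  low <- tr$intensity_au <= cutoff
  n <- nrow(tr)
  p <- config$persistence_frames
  for (i in seq_len(n)) {
    j <- min(n, i + p - 1L)
    if ((j - i + 1L) >= p && all(low[i:j]))
      return(data.frame(time_h = tr$timepoint_h[i], event = 1L,
                        call = "intensity"))
  }
  last <- tr$timepoint_h[n]
  if (config$disappearance_is_event && last < movie_end_h) {
    if (is.null(frame_interval_h))
      frame_interval_h <- if (n > 1) min(diff(tr$timepoint_h)) else
        movie_end_h - last
    return(data.frame(time_h = last + frame_interval_h, event = 1L,
                      call = "disappearance"))
  }
  data.frame(time_h = last, event = 0L, call = "censored")
}

#' Build survival records for all tracks
#'
#' Applies [call_death()] to every track in a track table. Manual
#' annotations (`cell_id`, `death_time_h`) override automated calls.
#'
#' @param tracks track table with `cell_id`, `timepoint_h` and a morphology
#'   intensity column (`mean_intensity_morphology` or `mean_intensity`).
#' @param background list with `mean` and `sd`.
#' @param config a [death_call_config()].
#' @param movie_end_h last imaged timepoint of the movie.
#' @param frame_interval_h imaging interval in hours.
#' @param group optional named vector mapping cell_id to group label.
#' @param manual optional data frame `cell_id, death_time_h`.
#' @param time_origin_h subtracted from all event/censoring times so that
#'   time 0 is the first imaging session (default: first timepoint in the
#'   table).
#' @return data frame of survival records: `cell_id, group, time_h, event,
#'   call`.
#' @export
survival_records <- function(tracks, background,
                             config = death_call_config(),
                             movie_end_h = max(tracks$timepoint_h),
                             frame_interval_h = NULL, group = NULL,
                             manual = NULL,
                             time_origin_h = min(tracks$timepoint_h)) {
  int_col <- intersect(c("mean_intensity_morphology", "mean_intensity",
                         "intensity_au"), names(tracks))[1]
  if (is.na(int_col)) stop("no intensity column found in `tracks`")
  ids <- sort(unique(tracks$cell_id))
  if (length(ids) == 0L)
    return(data.frame(cell_id = integer(0), group = character(0),
                      time_h = numeric(0), event = integer(0),
                      call = character(0)))
  out <- do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$cell_id == id, ]
    man <- if (!is.null(manual) && id %in% manual$cell_id)
      manual$death_time_h[match(id, manual$cell_id)] else NA_real_
    rec <- call_death(
      data.frame(timepoint_h = tr$timepoint_h,
                 intensity_au = tr[[int_col]]),
      background, config, movie_end_h = movie_end_h,
      frame_interval_h = frame_interval_h, manual_death_h = man)
    cbind(data.frame(cell_id = id,
                     group = if (!is.null(group))
                       group[[as.character(id)]] else "all"),
          rec)
  }))
  out$time_h <- out$time_h - time_origin_h
  rownames(out) <- NULL
  out
}

check_records <- function(records) {
  stopifnot(all(c("time_h", "event") %in% names(records)),
            all(records$event %in% c(0L, 1L)), all(records$time_h >= 0))
  if (!"group" %in% names(records)) records$group <- "all"
  records
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator; censored records reduce the risk set without
#' producing steps.
#'
#' @param records survival records (`time_h`, `event`, optional `group`).
#' @return data frame: `group, time_h, n_risk, n_event, n_censor,
#'   survival`, right-continuous step values at each observed time. The
#'   underlying `survival::survfit` object is attached as attribute
#'   `"survfit"`.
#' @export
km_curve <- function(records) {
  records <- check_records(records)
  single <- length(unique(records$group)) == 1L
  fit <- if (single)
    survival::survfit(survival::Surv(time_h, event) ~ 1, data = records)
  else
    survival::survfit(survival::Surv(time_h, event) ~ group, data = records)
  grp <- if (single) rep(records$group[1], length(fit$time))
         else rep(sub("^group=", "", names(fit$strata)), fit$strata)
  out <- data.frame(group = grp, time_h = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  attr(out, "survfit") <- fit
  out
}

#' Gehan-Breslow-Wilcoxon two-group test
#'
#' Weighted log-rank test with weights equal to the number at risk, which
#' emphasises early events. Implemented directly from the risk-table
#' algebra: at each distinct event time the weighted observed-minus-
#' expected events in group 1 are accumulated with hypergeometric variance.
#'
#' @param records survival records with exactly two groups.
#' @return list: `statistic` (chi-squared, 1 df), `p`, `U` (weighted
#'   observed - expected sum), `var_U`.
#' @export
gbw_test <- function(records) {
  records <- check_records(records)
  groups <- sort(unique(records$group))
  if (length(groups) != 2) stop("need exactly two groups")
  if (any(table(records$group) == 0)) stop("a group is empty")
  if (sum(records$event) == 0) stop("no events")
  g1 <- records$group == groups[1]
  etimes <- sort(unique(records$time_h[records$event == 1]))
  U <- 0; V <- 0
  for (t in etimes) {
    at_risk <- records$time_h >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(records$event == 1 & records$time_h == t)
    d1 <- sum(records$event == 1 & records$time_h == t & g1)
    e1 <- d * n1 / n
    v1 <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
    w <- n                       # Gehan weight: number at risk
    U <- U + w * (d1 - e1)
    V <- V + w^2 * v1
  }
  stat <- if (V > 0) U^2 / V else 0
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       U = U, var_U = V)
}

#' Cox proportional-hazards fit with group as the covariate
#'
#' Partial-likelihood fit (Efron tie handling — imaging grids create heavy
#' ties) with Wald 95% confidence interval on the hazard ratio. Complete
#' separation (a group with no events while the other has all early events)
#' yields an infinite hazard ratio with a warning.
#'
#' @param records survival records with two (or more) groups; the first
#'   group in sort order is the reference.
#' @return A `SurvivalFit` list: `hazard_ratio`, `ci_low`, `ci_high`,
#'   `coef`, `se`, `z`, `p_wald`, `lr_chisq`, `lr_p`, `reference`,
#'   `comparison`, plus the underlying `coxph` fit in `$fit`.
#' @export
cph_fit <- function(records) {
  records <- check_records(records)
  groups <- sort(unique(records$group))
  if (length(groups) < 2) stop("need at least two groups")
  records$group <- factor(records$group, levels = groups)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time_h, event) ~ group,
                    data = records, ties = "efron"))
  beta <- coef(fit)[1]
  se <- sqrt(fit$var[1, 1])
  if (!is.finite(beta) || abs(beta) > 20)
    warning("complete or near-complete separation: hazard ratio unstable")
  lr <- 2 * diff(fit$loglik)
  structure(list(
    hazard_ratio = exp(unname(beta)),
    ci_low = exp(unname(beta - 1.96 * se)),
    ci_high = exp(unname(beta + 1.96 * se)),
    coef = unname(beta), se = unname(se), z = unname(beta / se),
    p_wald = 2 * pnorm(-abs(unname(beta / se))),
    lr_chisq = unname(lr),
    lr_p = pchisq(unname(lr), df = length(coef(fit)),
                  lower.tail = FALSE),
    reference = groups[1], comparison = groups[2],
    fit = fit), class = "SurvivalFit")
}

#' @export
print.SurvivalFit <- function(x, ...) {
  cat(sprintf("<SurvivalFit> HR(%s vs %s) = %.3f, 95%% CI [%.3f, %.3f], Wald p = %.3g\n",
              x$comparison, x$reference, x$hazard_ratio, x$ci_low,
              x$ci_high, x$p_wald))
  invisible(x)
}

#' Nelson-Aalen cumulative hazard per group
#'
#' @param records survival records.
#' @return data frame: `group, time_h, cum_hazard` (nondecreasing from 0).
#' @export
cumulative_hazard <- function(records) {
  records <- check_records(records)
  do.call(rbind, lapply(split(records, records$group), function(d) {
    tt <- sort(unique(d$time_h[d$event == 1]))
    ch <- cumsum(vapply(tt, function(t)
      sum(d$event == 1 & d$time_h == t) / sum(d$time_h >= t), numeric(1)))
    if (length(tt) == 0)
      return(data.frame(group = d$group[1], time_h = numeric(0),
                        cum_hazard = numeric(0)))
    data.frame(group = d$group[1], time_h = tt, cum_hazard = ch)
  }))
}

#' Test linearity of the cumulative hazard (constancy of the hazard)
#'
#' A linear cumulative hazard is equivalent to a constant (exponential)
#' hazard rate. Tested by a likelihood-ratio comparison of Weibull versus
#' exponential parametric survival fits (group retained as a covariate):
#' the exponential model is the Weibull with shape fixed at 1, so the LR
#' statistic is chi-squared with 1 df under the constant-hazard null.
#' Nelson-Aalen cumulative hazard curves are returned for inspection.
#'
#' @param records survival records (>= 5 events required).
#' @return list: `chisq`, `p`, `weibull_shape` (estimated shape; 1 =
#'   constant hazard), `cum_hazard` (per-group Nelson-Aalen table).
#' @export
hazard_linearity <- function(records) {
  records <- check_records(records)
  if (sum(records$event) < 5)
    stop("too few events (< 5) for a hazard-linearity test")
  records <- records[records$time_h > 0, ]
  multi <- length(unique(records$group)) > 1
  fml <- if (multi) survival::Surv(time_h, event) ~ group
         else survival::Surv(time_h, event) ~ 1
  fw <- survival::survreg(fml, data = records, dist = "weibull")
  fe <- survival::survreg(fml, data = records, dist = "exponential")
  chisq <- as.numeric(2 * (logLik(fw) - logLik(fe)))
  chisq <- max(chisq, 0)
  list(chisq = chisq,
       p = pchisq(chisq, df = 1, lower.tail = FALSE),
       weibull_shape = 1 / fw$scale,
       cum_hazard = cumulative_hazard(records))
}
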