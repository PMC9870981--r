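#' Printed endpoint summary statistics of the hemorrhage-resuscitation study
#'
#' The per-group `(mean, SD, n)` rows for the seven endpoints reported in the
#' study: the glycocalyx index of 40-um and 60-um arteries (um), plasma
#' syndecan-1 (ng/mL), and the blood-gas endpoints pH, base excess (mEq/L),
#' lactate (mmol/L) and hemoglobin (g/dL), for the control group C and the
#' five resuscitation groups. `flag` is the published significance mark for
#' the comparison with group C (`"*"` p <= 0.05, `"**"` p <= 0.01). These
#' printed summaries are the input from which the package re-derives the
#' study's ANOVA/Dunnett inferences.
#'
#' @param endpoint optional endpoint name to filter on (one of
#'   `"GCXI-40"`, `"GCXI-60"`, `"syndecan-1"`, `"pH"`, `"BE"`, `"lactate"`,
#'   `"Hb"`).
#' @return data frame with columns `endpoint`, `units`, `group`, `n`, `mean`,
#'   `sd`, `flag`.
#' @export
study_endpoint_summaries <- function(endpoint = NULL) {
  g <- c("C", "NS-NS", "NS-ALB", "ALB-NS", "NS-HES", "HES-NS")
  row <- function(ep, units, n, mean, sd, flag) {
    data.frame(endpoint = ep, units = units, group = g, n = n, mean = mean,
               sd = sd, flag = flag)
  }
  out <- rbind(
    row("GCXI-40", "um", c(7, 7, 8, 8, 8, 6),
        c(5.69, 3.69, 3.31, 3.40, 2.96, 3.28),
        c(1.99, 0.91, 1.04, 1.15, 0.53, 0.66),
        c("", "**", "**", "**", "**", "**")),
    row("GCXI-60", "um", c(10, 9, 8, 7, 10, 8),
        c(4.93, 3.76, 3.77, 4.04, 3.28, 4.82),
        c(1.45, 0.80, 0.80, 1.27, 1.07, 0.88),
        c("", "*", "*", "", "**", "")),
    row("syndecan-1", "ng/mL", c(9, 7, 5, 6, 6, 8),
        c(2.54, 7.70, 3.00, 5.99, 2.11, 2.76),
        c(0.69, 5.71, 0.92, 3.04, 0.44, 1.33),
        c("", "**", "", "", "", "")),
    row("pH", "", c(10, 8, 8, 7, 8, 8),
        c(7.172, 6.980, 7.068, 7.037, 7.088, 7.077),
        c(0.058, 0.070, 0.052, 0.069, 0.051, 0.055),
        c("", "**", "**", "**", "*", "**")),
    row("BE", "mEq/L", c(10, 8, 8, 7, 8, 8),
        c(1.8, -11.5, -6.1, -7.4, -4.4, -4.5),
        c(1.48, 4.21, 3.44, 4.04, 1.77, 2.00),
        c("", "**", "**", "**", "**", "**")),
    row("lactate", "mmol/L", c(10, 8, 8, 6, 8, 8),
        c(0.8, 4.2, 2.9, 3.9, 1.8, 1.2),
        c(0.51, 0.99, 1.34, 1.37, 1.71, 0.56),
        c("", "**", "**", "**", "", "")),
    row("Hb", "g/dL", c(10, 8, 8, 6, 8, 8),
        c(13.7, 6.5, 4.3, 7.3, 5.6, 6.7),
        c(1.06, 1.36, 1.45, 0.98, 1.18, 0.56),
        c("", "**", "**", "**", "**", "**"))
  )
  if (!is.null(endpoint)) {
    if (!endpoint %in% out$endpoint)
      gcxi_error(sprintf("unknown endpoint '%s'", endpoint),
                 "gcxi_bad_summary")
    out <- out[out$endpoint == endpoint, ]
    rownames(out) <- NULL
  }
  out
}

#' Cohort specification for synthetic endpoint and survival simulation
#'
#' Defines, per group and endpoint, the normal distribution `(mean, sd, n)`
#' from which per-mouse endpoint values are drawn, and per group a constant
#' weekly death probability for the survival simulation. The default endpoint
#' table is the study's printed summary statistics
#' ([study_endpoint_summaries()]); the weekly death probabilities are free
#' parameters with a neutral default of 0.5 for every group.
#'
#' @param endpoints data frame with columns `endpoint`, `group`, `n`, `mean`,
#'   `sd`.
#' @param weekly_death_prob named numeric vector in `[0, 1]`, one entry per
#'   group.
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(endpoints = study_endpoint_summaries(),
                        weekly_death_prob = NULL, seed = 1L) {
  stopifnot(is.data.frame(endpoints),
            all(c("endpoint", "group", "n", "mean", "sd") %in%
                  names(endpoints)))
  if (any(endpoints$n < 2))
    gcxi_error("each group x endpoint needs n >= 2", "gcxi_bad_cohort")
  if (any(endpoints$sd < 0))
    gcxi_error("sd must be >= 0", "gcxi_bad_cohort")
  groups <- unique(endpoints$group)
  weekly_death_prob <- weekly_death_prob %||%
    setNames(rep(0.5, length(groups)), groups)
  if (any(weekly_death_prob < 0 | weekly_death_prob > 1))
    gcxi_error("death probabilities must lie in [0, 1]", "gcxi_bad_cohort")
  structure(list(endpoints = endpoints,
                 weekly_death_prob = weekly_death_prob,
                 groups = groups, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a per-mouse endpoint table
#'
#' For each group x endpoint cell, draws `n` independent normal values with
#' the specified mean and SD. Reproducible under the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return data frame `subject`, `group`, `endpoint`, `value`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ep <- spec$endpoints
  with_seed(spec$seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(ep)), function(i) {
      data.frame(
        subject = sprintf("%s-%s-%02d", ep$group[i], ep$endpoint[i],
                          seq_len(ep$n[i])),
        group = ep$group[i], endpoint = ep$endpoint[i],
        value = rnorm(ep$n[i], ep$mean[i], ep$sd[i]))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate seven-day survival records
#'
#' Each group's constant weekly death probability `p` is converted to the
#' exponential hazard `-log(1 - p) / 7` per day; event times beyond the
#' horizon are censored at the horizon. A probability of 1 produces immediate
#' deaths (time `1e-6` days).
#'
#' @param spec a [cohort_spec()].
#' @param n_per_group subjects per group; a single number or a named vector.
#' @param horizon_days follow-up horizon, days (> 0; default 7).
#' @return data frame `subject`, `group`, `time` (days), `event` (1 death,
#'   0 censored at horizon).
#' @export
simulate_survival <- function(spec, n_per_group = 10L, horizon_days = 7) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is_number(horizon_days) || horizon_days <= 0)
    gcxi_error("horizon must be > 0", "gcxi_bad_cohort")
  groups <- names(spec$weekly_death_prob)
  n <- if (length(n_per_group) == 1) setNames(rep(n_per_group, length(groups)),
                                              groups) else n_per_group[groups]
  with_seed(spec$seed, {
    out <- do.call(rbind, lapply(groups, function(gr) {
      p <- spec$weekly_death_prob[[gr]]
      hazard <- if (p >= 1) Inf else -log(1 - p) / 7
      tm <- if (is.infinite(hazard)) rep(1e-6, n[[gr]])
      else if (hazard == 0) rep(Inf, n[[gr]])
      else rexp(n[[gr]], hazard)
      event <- as.integer(tm <= horizon_days)
      tm[event == 0] <- horizon_days
      data.frame(subject = sprintf("%s-%02d", gr, seq_len(n[[gr]])),
                 group = gr, time = tm, event = event)
    }))
    rownames(out) <- NULL
    out
  })
}
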