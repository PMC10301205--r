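#' Simulation configuration for synthetic cohorts
#'
#' Defines the generative model of the synthetic-cohort module. Each
#' individual carries a mean-one log-normal frailty (shared susceptibility
#' across endpoints). On each day, every absent non-mortality endpoint
#' switches on with probability
#' `plogis(qlogis(baseline * multiplier^exponent) + log(frailty) +
#' sum(log driver odds))`, where driver coupling uses the endpoint states of
#' the previous day (drivers precede their targets by one day). Endpoints
#' are absorbing. Mortality is then drawn with an extra burden term
#' proportional to the number of active abnormalities; death is absorbing
#' and freezes the other endpoints (carry-forward), reproducing survival
#' bias. Delayed swim bladder inflation is structurally 0 before 4 dpf.
#'
#' The default design mirrors a 4-arm zebrafish exposure study: vehicle
#' control plus three concentrations (0.5, 1, 5 micromolar), 30 embryos per
#' arm, observed daily 2-7 dpf. Default hazards and coupling encode the
#' edema-driver structure such studies report: pericardial and yolk sac
#' edema at moderate daily onset act as mutually coupled drivers preceding
#' the rarer downstream endpoints. Driver incidence stays mid-range over
#' the window — the regime in which pairwise exact tests are informative;
#' endpoints near 0% or 100% prevalence yield degenerate tables and carry
#' no association signal.
#'
#' @param groups Named numeric vector: group label -> concentration
#'   multiplier (0 for the control).
#' @param n_per_group Individuals per group (>= 1).
#' @param timepoints Integer dpf vector (default 2:7).
#' @param baseline_hazard Named per-day onset probability at multiplier 1,
#'   one entry per catalog endpoint (M = mortality baseline).
#' @param concentration_exponent Exponent of the multiplier in the dose
#'   scaling `baseline * multiplier^exponent`.
#' @param frailty_sd Standard deviation of log frailty (0 disables shared
#'   susceptibility, making endpoints independent).
#' @param coupling Named list: driver endpoint -> named numeric vector of
#'   target endpoint -> odds multiplier, applied when the driver was present
#'   the previous day.
#' @param mortality_burden_coeff Added log-odds of death per active
#'   abnormality.
#' @param seed Integer master seed; each (group, individual) derives its own
#'   substream, so changing one group's n never reshuffles another group.
#' @param catalog An [outcome_catalog()].
#' @return A `simulation_config`.
#' @seealso [simulate_cohort()], [scenario_library()]
#' @export
simulation_config <- function(groups = c(control = 0, "0.5uM" = 0.5,
                                         "1uM" = 1, "5uM" = 5),
                              n_per_group = 30,
                              timepoints = 2:7,
                              baseline_hazard = c(PE = 0.14, YSE = 0.14,
                                                  CM = 0.005, SD = 0.005,
                                                  SBI = 0.008, M = 0.01),
                              concentration_exponent = 0.3,
                              frailty_sd = 0.15,
                              coupling = list(
                                PE = c(YSE = 10, CM = 3, SD = 3, SBI = 3,
                                       M = 3),
                                YSE = c(PE = 10, CM = 3, SD = 3, SBI = 3,
                                        M = 3)
                              ),
                              mortality_burden_coeff = 0.5,
                              seed = 1,
                              catalog = outcome_catalog()) {
  if (is.null(names(groups)) || any(names(groups) == "") ||
      anyDuplicated(names(groups))) {
    stop_validation("groups must be a uniquely named numeric vector",
                    "dynetox_bad_config")
  }
  if (any(groups < 0) || n_per_group < 1 ||
      any(timepoints != round(timepoints))) {
    stop_validation("invalid group multipliers, n_per_group or timepoints",
                    "dynetox_bad_config")
  }
  if (!all(catalog$labels %in% names(baseline_hazard)) ||
      any(baseline_hazard < 0) || any(baseline_hazard > 1)) {
    stop_validation(
      "baseline_hazard needs one probability in [0,1] per endpoint",
      "dynetox_bad_config"
    )
  }
  for (drv in names(coupling)) {
    tgt <- coupling[[drv]]
    if (!drv %in% catalog$labels || !all(names(tgt) %in% catalog$labels) ||
        any(tgt <= 0)) {
      stop_validation("coupling must map endpoints to positive odds",
                      "dynetox_bad_config")
    }
  }
  if (frailty_sd < 0) {
    stop_validation("frailty_sd must be >= 0", "dynetox_bad_config")
  }
  structure(list(
    groups = groups,
    n_per_group = as.integer(n_per_group),
    timepoints = as.integer(sort(timepoints)),
    baseline_hazard = baseline_hazard[catalog$labels],
    concentration_exponent = concentration_exponent,
    frailty_sd = frailty_sd,
    coupling = coupling,
    mortality_burden_coeff = mortality_burden_coeff,
    seed = as.integer(seed),
    catalog = catalog
  ), class = "simulation_config")
}

# Deterministic per-individual substream seed below 2^31, independent of
# the n of other groups.
individual_seed <- function(seed, group_idx, indiv_idx) {
  as.integer((abs(as.numeric(seed)) * 20011 + group_idx * 131071 +
                indiv_idx * 8191) %% 2147483647)
}

onset_prob <- function(base, log_frailty, extra_logodds) {
  if (base <= 0) return(0)
  stats::plogis(stats::qlogis(base) + log_frailty + extra_logodds)
}

#' Simulate a synthetic cohort
#'
#' Generates a `cohort_study` under the generative model described in
#' [simulation_config()]. Identical seed and configuration yield an
#' identical cohort (and identical CSV bytes through [write_cohort()]).
#' Dose-scaled baselines above 0.99 are clamped with a warning.
#'
#' @param config A [simulation_config()].
#' @return A validated `cohort_study`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  catalog <- config$catalog
  labels <- catalog$labels
  non_m <- setdiff(labels, "M")
  tps <- config$timepoints
  clamped <- FALSE

  rows <- vector("list", length(config$groups) * config$n_per_group)
  ri <- 0L
  for (gi in seq_along(config$groups)) {
    glab <- names(config$groups)[gi]
    mult <- config$groups[[gi]]
    scale <- if (mult > 0) mult^config$concentration_exponent else 0
    base <- pmin(config$baseline_hazard * scale, 0.99)
    if (any(config$baseline_hazard * scale > 0.99)) clamped <- TRUE

    for (k in seq_len(config$n_per_group)) {
      set.seed(individual_seed(config$seed, gi, k))
      # mean-one log-normal frailty; draw even when sd = 0 to keep the
      # substream layout identical across configurations
      z <- stats::rnorm(1)
      lf <- if (config$frailty_sd > 0)
        config$frailty_sd * z - config$frailty_sd^2 / 2 else 0

      status <- stats::setNames(integer(length(non_m)), non_m)
      alive <- TRUE
      dead_day <- NA_integer_
      obs <- matrix(0L, nrow = length(tps), ncol = length(labels),
                    dimnames = list(NULL, labels))
      prev_status <- status
      for (ti in seq_along(tps)) {
        t <- tps[ti]
        if (alive) {
          for (e in non_m) {
            if (status[[e]] == 1L) next
            if (e == "SBI" && t < 4L) next
            extra <- 0
            for (drv in names(config$coupling)) {
              tgt <- config$coupling[[drv]]
              if (!is.na(tgt[e]) && drv %in% non_m &&
                  prev_status[[drv]] == 1L) {
                extra <- extra + log(tgt[[e]])
              }
            }
            p <- onset_prob(base[[e]], lf, extra)
            if (p > 0 && stats::runif(1) < p) status[[e]] <- 1L
          }
          burden <- sum(status)
          pm <- onset_prob(base[["M"]], lf,
                           config$mortality_burden_coeff * burden)
          if (pm > 0 && stats::runif(1) < pm) {
            alive <- FALSE
            dead_day <- t
          }
        }
        obs[ti, non_m] <- status
        obs[ti, "M"] <- as.integer(!alive)
        prev_status <- status
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        individual_id = sprintf("%s_%03d", sanitize_label(glab), k),
        group = glab,
        dpf = tps,
        obs,
        stringsAsFactors = FALSE
      )
    }
  }
  if (clamped) {
    warning("dose-scaled onset probability exceeded 0.99 and was clamped")
  }
  cohort_study(do.call(rbind, rows), catalog)
}

#' Library of named simulation scenarios
#'
#' Four qualitative regimes spanning the behaviors a co-occurrence analysis
#' must distinguish:
#' \describe{
#'   \item{control}{no signal anywhere: zero baselines, no frailty, no
#'     coupling — every downstream association is p = 1 and all centrality
#'     is zero.}
#'   \item{low}{sparse, late co-occurrence: weak baselines, mild shared
#'     frailty and coupling, negligible mortality.}
#'   \item{high}{strong co-occurrence from early days: pericardial and yolk
#'     sac edema act as drivers with strong (odds 6) coupling into the
#'     remaining endpoints, low mortality so associations keep developing.}
#'   \item{lethal}{the high regime plus heavy, abnormality-linked early
#'     mortality: death freezes further onsets, so late-day association
#'     scores fall below the high regime despite the higher insult —
#'     survival bias — while mortality's coupling to the abnormality burden
#'     produces links already at the first observation day.}
#' }
#'
#' @param seed Master seed stored in each config.
#' @param n_per_group Individuals per group.
#' @param groups Named group -> multiplier vector, shared by all scenarios
#'   (defaults to the 4-arm design of [simulation_config()]).
#' @return Named list of [simulation_config()] objects.
#' @export
scenario_library <- function(seed = 1, n_per_group = 30,
                             groups = c(control = 0, "0.5uM" = 0.5,
                                        "1uM" = 1, "5uM" = 5)) {
  list(
    control = simulation_config(
      baseline_hazard = c(PE = 0, YSE = 0, CM = 0, SD = 0, SBI = 0, M = 0),
      frailty_sd = 0, coupling = list(), mortality_burden_coeff = 0,
      seed = seed, n_per_group = n_per_group, groups = groups
    ),
    low = simulation_config(
      baseline_hazard = c(PE = 0.06, YSE = 0.06, CM = 0.003, SD = 0.003,
                          SBI = 0.005, M = 0.005),
      frailty_sd = 0.15,
      coupling = list(PE = c(YSE = 5, CM = 2, SD = 2, SBI = 2, M = 2),
                      YSE = c(PE = 5, CM = 2, SD = 2, SBI = 2, M = 2)),
      mortality_burden_coeff = 0.3,
      seed = seed, n_per_group = n_per_group, groups = groups
    ),
    high = simulation_config(seed = seed, n_per_group = n_per_group,
                             groups = groups),
    lethal = simulation_config(
      baseline_hazard = c(PE = 0.14, YSE = 0.14, CM = 0.005, SD = 0.005,
                          SBI = 0.008, M = 0.22),
      mortality_burden_coeff = 1.2,
      seed = seed, n_per_group = n_per_group, groups = groups
    )
  )
}

#' Fetch one named scenario
#'
#' @param name One of `"control"`, `"low"`, `"high"`, `"lethal"`.
#' @inheritParams scenario_library
#' @return A [simulation_config()].
#' @export
get_scenario <- function(name, seed = 1, n_per_group = 30,
                         groups = c(control = 0, "0.5uM" = 0.5,
                                    "1uM" = 1, "5uM" = 5)) {
  lib <- scenario_library(seed = seed, n_per_group = n_per_group,
                          groups = groups)
  if (!name %in% names(lib)) {
    stop_validation(paste0("unknown scenario '", name, "'; available: ",
                           paste(names(lib), collapse = ", ")),
                    "dynetox_unknown_scenario")
  }
  lib[[name]]
}
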