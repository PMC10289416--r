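#' Scenario specification
#'
#' A declarative description of how a screening scenario transforms
#' baseline inputs: which groups flip to screening, which groups inherit
#' another group's conditional stage distribution, multiplicative or
#' absolute incidence changes, a global treatment-cost scale, and an
#' additive localized-vs-regional stage shift.
#'
#' @param name scenario label.
#' @param policy policy vector of the scenario.
#' @param stage_substitutions list of \code{list(target = j, source = j)}:
#'   the target group's conditional stage distribution under its scenario
#'   status becomes the source group's distribution under the baseline
#'   policy.
#' @param incidence_multipliers list of \code{list(j = , factor = )}:
#'   the scenario incidence of group \code{j} is the baseline incidence
#'   (under the baseline policy status) times \code{factor}.
#' @param incidence_overrides named numeric vector (names = group index):
#'   absolute replacement incidence rates under the scenario status.
#' @param cost_scale multiplicative factor on all treatment-cost cells
#'   (screening unit cost unchanged).
#' @param stage_shift list \code{list(delta = , groups = )}: move
#'   \code{delta} conditional probability mass from stage 2 (regional) to
#'   stage 1 (localized) for the listed groups (negative \code{delta}
#'   moves it the other way).
#' @return an object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(name, policy,
                          stage_substitutions = list(),
                          incidence_multipliers = list(),
                          incidence_overrides = NULL,
                          cost_scale = 1,
                          stage_shift = NULL) {
  if (cost_scale <= 0) stop("cost_scale must be > 0")
  structure(list(name = name, policy = policy,
                 stage_substitutions = stage_substitutions,
                 incidence_multipliers = incidence_multipliers,
                 incidence_overrides = incidence_overrides,
                 cost_scale = cost_scale,
                 stage_shift = stage_shift),
            class = "scenario_spec")
}

#' Apply a scenario specification to baseline inputs
#'
#' Pure transformation: the baseline object is not modified. The result is
#' validated before it is returned.
#'
#' @param baseline a validated \code{model_inputs}.
#' @param spec a \code{scenario_spec}.
#' @param baseline_policy the policy under which the baseline incidence and
#'   stage estimates were observed (default: screening at ages 50-69).
#' @return list with \code{inputs} (transformed \code{model_inputs}),
#'   \code{policy} and \code{name}.
#' @export
apply_scenario <- function(baseline, spec,
                           baseline_policy = finnish_current_policy(baseline$grid)) {
  assert_valid(baseline)
  check_policy(baseline_policy, baseline$grid)
  h <- spec$policy
  check_policy(h, baseline$grid)
  inc <- baseline$incidence
  q <- baseline$stages

  for (sub in spec$stage_substitutions) {
    tgt <- sub$target; src <- sub$source
    if (src < 1 || src > baseline$grid$J) {
      stop("stage substitution source group ", src, " does not exist")
    }
    q[tgt, h[tgt], ] <- baseline$stages[src, baseline_policy[src], ]
  }
  for (m in spec$incidence_multipliers) {
    j <- m$j
    if (m$factor <= 0) stop("incidence multiplier must be > 0")
    inc[j, h[j]] <- baseline$incidence[j, baseline_policy[j]] * m$factor
  }
  if (!is.null(spec$incidence_overrides)) {
    js <- as.integer(names(spec$incidence_overrides))
    for (i in seq_along(js)) {
      inc[js[i], h[js[i]]] <- spec$incidence_overrides[[i]]
    }
  }
  cm <- baseline$cost_model
  if (spec$cost_scale != 1) cm <- scale_treatment_costs(cm, spec$cost_scale)

  if (!is.null(spec$stage_shift)) {
    delta <- spec$stage_shift$delta
    for (j in spec$stage_shift$groups) {
      for (s in STATUS_LEVELS) {
        q[j, s, "k1"] <- q[j, s, "k1"] + delta
        q[j, s, "k2"] <- q[j, s, "k2"] - delta
        if (q[j, s, "k1"] < 0 || q[j, s, "k2"] < 0) {
          stop(sprintf(
            "stage shift %+g makes q(j=%d, %s) negative", delta, j, s))
        }
      }
    }
  }

  out <- model_inputs(baseline$grid, inc, q, baseline$survival,
                      baseline$causes, cm, baseline$N0)
  assert_valid(out)
  list(name = spec$name, inputs = out, policy = h)
}

#' Extend screening to the younger age groups (46-49)
#'
#' Groups 46-47 and 48-49 flip to screening. Their conditional stage
#' distributions are extrapolated from the closest screened groups under
#' the current policy: 46-47 takes 50-51's distribution, 48-49 and 50-51
#' take 52-53's. The first-screen (prevalence) effect and the shift of
#' detections to earlier ages are modelled as incidence adjustments: +28\%
#' for 46-47, +24.7\% for 48-49, and -11.9\% for 50-51.
#'
#' @param baseline a validated \code{model_inputs} with \code{J >= 4}.
#' @param baseline_policy the current policy (default screening 50-69).
#' @return list with \code{name}, \code{inputs}, \code{policy}.
#' @export
build_younger_extension <- function(baseline,
                                    baseline_policy = finnish_current_policy(baseline$grid)) {
  if (baseline$grid$J < 4L) {
    stop("younger extension needs source groups 50-51 and 52-53 (J >= 4)")
  }
  h <- baseline_policy
  h[1:2] <- "S"
  spec <- scenario_spec(
    name = "46-69 yr",
    policy = h,
    stage_substitutions = list(list(target = 1L, source = 3L),
                               list(target = 2L, source = 4L),
                               list(target = 3L, source = 4L)),
    incidence_multipliers = list(list(j = 1L, factor = 1.28),
                                 list(j = 2L, factor = 1.247),
                                 list(j = 3L, factor = 0.881)))
  apply_scenario(baseline, spec, baseline_policy)
}

#' Extend screening to the older age groups (70-73)
#'
#' Groups 70-71 and 72-73 flip to screening and inherit the conditional
#' stage distribution of the oldest screened group (68-69); every group
#' above 73 inherits the baseline distribution of the group two positions
#' (four years) younger, shifting the old-age stage profile outward.
#' Incidence above age 69 is replaced by externally supplied rates (e.g. a
#' steady-state decline pattern such as Sweden's); these are a
#' configuration input, not a packaged constant.
#'
#' @param baseline a validated \code{model_inputs}.
#' @param older_incidence named numeric vector of replacement incidence
#'   rates, names = group indices above the last currently screened group.
#'   Must cover every newly screened group. \code{NULL} with empty
#'   \code{flip_groups} returns the baseline unchanged.
#' @param flip_groups group indices flipped to screening (default 13:14,
#'   ages 70-73).
#' @param baseline_policy the current policy.
#' @return list with \code{name}, \code{inputs}, \code{policy}.
#' @export
build_older_extension <- function(baseline, older_incidence = NULL,
                                  flip_groups = c(13L, 14L),
                                  baseline_policy = finnish_current_policy(baseline$grid)) {
  if (is.null(older_incidence) && length(flip_groups) == 0L) {
    return(list(name = "50-69 yr", inputs = baseline,
                policy = baseline_policy))
  }
  if (is.null(older_incidence) ||
      !all(as.character(flip_groups) %in% names(older_incidence))) {
    stop("older_incidence overrides must cover every newly screened group (",
         paste(flip_groups, collapse = ", "), ")")
  }
  J <- baseline$grid$J
  h <- baseline_policy
  h[flip_groups] <- "S"
  first_new <- min(flip_groups)
  anchor <- first_new - 1L # oldest currently screened group (68-69)
  subs <- lapply(flip_groups, function(j) list(target = j, source = anchor))
  shift_from <- max(flip_groups) + 1L
  if (shift_from <= J) {
    subs <- c(subs, lapply(shift_from:J,
                           function(j) list(target = j, source = j - 2L)))
  }
  spec <- scenario_spec(name = "50-74 yr", policy = h,
                        stage_substitutions = subs,
                        incidence_overrides = older_incidence)
  apply_scenario(baseline, spec, baseline_policy)
}

#' Extend screening in both directions (46-73)
#'
#' Composition of the younger and older extensions; the two touch disjoint
#' age ranges apart from the shared reference machinery, so the order
#' (younger first, then older) does not affect the result.
#'
#' @inheritParams build_older_extension
#' @return list with \code{name}, \code{inputs}, \code{policy}.
#' @export
build_both_extension <- function(baseline, older_incidence,
                                 flip_groups = c(13L, 14L),
                                 baseline_policy = finnish_current_policy(baseline$grid)) {
  young <- build_younger_extension(baseline, baseline_policy)
  # the older substitutions/overrides read from the untouched old-age range,
  # so applying them on top of the younger result is exact composition
  old <- build_older_extension(young$inputs, older_incidence, flip_groups,
                               baseline_policy)
  h <- old$policy
  h[1:2] <- "S"
  out <- old$inputs
  list(name = "46-74 yr", inputs = out, policy = h)
}

#' One-way sensitivity transformations
#'
#' Perturbs exactly one model dimension, leaving everything else as in the
#' main scenario: modelled incidence rates +/-10\% (for the age groups the
#' scenario models), all treatment costs +10\% or +50\% (screening cost
#' unchanged), or +/-0.02 conditional probability moved between localized
#' (stage 1) and regional (stage 2) disease for the modelled groups.
#'
#' @param inputs scenario \code{model_inputs}.
#' @param which one of \code{"incidence_up"}, \code{"incidence_down"},
#'   \code{"costs_up_10"}, \code{"costs_up_50"}, \code{"stage_up"},
#'   \code{"stage_down"}.
#' @param groups age-group indices the scenario models (the sensitivity
#'   only touches these for incidence and stage variants).
#' @return a new validated \code{model_inputs}.
#' @export
apply_sensitivity <- function(inputs,
                              which = c("incidence_up", "incidence_down",
                                        "costs_up_10", "costs_up_50",
                                        "stage_up", "stage_down"),
                              groups = seq_len(inputs$grid$J)) {
  which <- match.arg(which)
  assert_valid(inputs)
  inc <- inputs$incidence
  q <- inputs$stages
  cm <- inputs$cost_model
  if (which %in% c("incidence_up", "incidence_down")) {
    f <- if (which == "incidence_up") 1.1 else 0.9
    inc[groups, ] <- inc[groups, ] * f
    if (any(inc > 1)) stop("incidence sensitivity pushes a rate above 1")
  } else if (which %in% c("costs_up_10", "costs_up_50")) {
    f <- if (which == "costs_up_10") 1.1 else 1.5
    cm <- scale_treatment_costs(cm, f)
  } else {
    delta <- if (which == "stage_up") 0.02 else -0.02
    q[groups, , "k1"] <- q[groups, , "k1"] + delta
    q[groups, , "k2"] <- q[groups, , "k2"] - delta
    if (any(q < 0)) {
      stop("stage shift ", delta, " produces a negative conditional probability")
    }
  }
  out <- model_inputs(inputs$grid, inc, q, inputs$survival, inputs$causes,
                      cm, inputs$N0)
  assert_valid(out)
  out
}
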