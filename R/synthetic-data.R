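#' Configuration for the synthetic parameter generator
#'
#' The generator emulates the statistical structure of the Finnish
#' screening inputs — age-increasing incidence with a first-screen
#' prevalence peak and a post-screening deficit, stage distributions
#' favouring localized disease under screening, survival with excess
#' breast-cancer mortality decaying to background within 18 years, and a
#' stage-graded breast-cancer vs other-cause death split — without
#' reproducing any registry value. All emitted inputs are synthetic.
#'
#' @param seed integer RNG seed; the generator is deterministic given the
#'   full configuration.
#' @param J number of 2-year age groups.
#' @param base_incidence 2-year diagnosis probability at age 46 without
#'   screening.
#' @param incidence_slope relative incidence increase per year of age.
#' @param screen_effect fraction of regional/distant conditional mass
#'   reallocated to localized/in-situ disease under screening (stage
#'   shift; 0 disables it).
#' @param screen_detection_boost relative incidence increase under
#'   screening (earlier detection of prevalent disease).
#' @param first_screen_bump extra relative incidence at the youngest
#'   screened group's first invitation (default 0.28).
#' @param post_screen_deficit relative incidence deficit in the first
#'   groups after screening stops (cancers already detected).
#' @param excess_mortality_decay_years years after diagnosis at which
#'   excess breast-cancer mortality has decayed to zero (default 18).
#' @param excess_hazard_by_stage annual excess death hazard at diagnosis,
#'   stages 0-4.
#' @param bc_death_share_by_stage probability that a death at diagnosis
#'   time is attributed to breast cancer, stages 0-4 (fades to zero with
#'   the excess-mortality decay).
#' @param background_life_table optional named numeric vector of annual
#'   death probabilities by age (ages 46..horizon-1); a Gompertz-type
#'   default is built when NULL.
#' @param screened_ages length-2 vector: inclusive age range of the
#'   reference screening policy used to place the first-screen bump and
#'   post-screening deficit.
#' @param noise_sd standard deviation of the seeded log-normal wiggle on
#'   incidence and stage parameters (makes distinct seeds distinct
#'   fixtures).
#' @param horizon_age survival horizon (default 100).
#' @param N0 initial cohort size (default 100000).
#' @return an object of class \code{generator_config}.
#' @export
generator_config <- function(seed = 1L, J = 27L,
                             base_incidence = 0.004,
                             incidence_slope = 0.02,
                             screen_effect = 0.10,
                             screen_detection_boost = 0.10,
                             first_screen_bump = 0.28,
                             post_screen_deficit = 0.12,
                             excess_mortality_decay_years = 18,
                             excess_hazard_by_stage =
                               c(0.05, 0.015, 0.08, 0.30, 0.004),
                             bc_death_share_by_stage =
                               c(0.45, 0.20, 0.55, 0.85, 0.03),
                             background_life_table = NULL,
                             screened_ages = c(50, 69),
                             noise_sd = 0.08,
                             horizon_age = 100L,
                             N0 = 1e5) {
  cfg <- structure(as.list(environment()), class = "generator_config")
  probs <- c(screen_effect, screen_detection_boost, first_screen_bump,
             post_screen_deficit, bc_death_share_by_stage)
  if (any(probs < 0) || any(bc_death_share_by_stage > 1) ||
      screen_effect > 1 || post_screen_deficit > 1) {
    stop("generator probabilities must lie in [0, 1]")
  }
  if (excess_mortality_decay_years > horizon_age - 46) {
    stop("excess-mortality decay exceeds the survival support")
  }
  cfg
}

default_life_table <- function(horizon_age) {
  ages <- 46:(horizon_age - 1L)
  q <- pmin(0.7, 0.0012 * exp(0.095 * (ages - 46)))
  q[ages >= horizon_age - 1L] <- 1 # no one survives past the horizon
  names(q) <- ages
  q
}

#' Generate a complete synthetic model-input set
#'
#' See \code{\link{generator_config}} for what is emulated. The output
#' always passes \code{\link{validate_inputs}}; a configuration that would
#' produce an invalid probability errors before anything is emitted. The
#' packaged treatment-cost tables (\code{\link{paper_fixture}}) are used as
#' the cost model.
#'
#' @param config a \code{generator_config}.
#' @return a validated \code{model_inputs}.
#' @export
generate_inputs <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  grid <- age_grid(config$J, config$horizon_age)
  J <- grid$J
  ages <- lower_age(grid, seq_len(J))
  ref_policy <- screening_policy(grid, config$screened_ages[1],
                                 config$screened_ages[2])
  screened <- which(ref_policy == "S")

  # --- incidence: rising with age, seeded wiggle ------------------------
  iota0 <- config$base_incidence *
    (1 + config$incidence_slope * (ages - 46)) *
    exp(stats::rnorm(J, 0, config$noise_sd))
  iota_ns <- iota0
  if (length(screened) > 0L) {
    post <- which(seq_len(J) > max(screened))
    post <- utils::head(post, 2L) # deficit fades after two groups
    fade <- c(1, 0.5)[seq_along(post)]
    iota_ns[post] <- iota_ns[post] * (1 - config$post_screen_deficit * fade)
  }
  iota_s <- iota0 * (1 + config$screen_detection_boost)
  if (length(screened) > 0L) {
    iota_s[min(screened)] <- iota_s[min(screened)] *
      (1 + config$first_screen_bump)
  }
  incidence <- cbind(S = pmin(iota_s, 1), NS = pmin(iota_ns, 1))

  # --- conditional stage distributions ----------------------------------
  q_base <- c(0.10, 0.44, 0.32, 0.03, 0.11)
  stages <- array(0, dim = c(J, 2L, 5L),
                  dimnames = list(NULL, STATUS_LEVELS, DIAG_STAGE_LABELS))
  for (j in seq_len(J)) {
    drift <- min(0.10, 0.002 * (ages[j] - 46)) # older: more advanced stage
    qn <- q_base + c(0, -drift, drift * 0.8, drift * 0.2, 0)
    qn <- qn * exp(stats::rnorm(5, 0, config$noise_sd / 2))
    qn <- qn / sum(qn)
    e <- config$screen_effect
    moved <- e * (qn[3] + qn[4])
    qs <- qn
    qs[3] <- qn[3] * (1 - e)
    qs[4] <- qn[4] * (1 - e)
    qs[2] <- qn[2] + 0.8 * moved
    qs[5] <- qn[5] + 0.2 * moved
    stages[j, "NS", ] <- qn
    stages[j, "S", ] <- qs
  }

  # --- survival and cause-of-death laws ---------------------------------
  lt <- config$background_life_table
  if (is.null(lt)) lt <- default_life_table(config$horizon_age)
  max_t <- config$horizon_age - 1L - ages[1L]
  Tn <- max_t + 1L
  mort_scale <- exp(stats::rnorm(1, 0, config$noise_sd))
  survival <- array(0, dim = c(J, 6L, Tn),
                    dimnames = list(NULL, STAGE_LABELS, NULL))
  causes <- array(0, dim = c(J, 5L, Tn, 2L),
                  dimnames = list(NULL, DIAG_STAGE_LABELS, NULL, c("d1", "d2")))
  decay <- config$excess_mortality_decay_years
  for (j in seq_len(J)) {
    tj <- config$horizon_age - 1L - ages[j]
    tv <- 0:tj
    qbg <- pmin(1, unname(lt[as.character(ages[j] + tv)]) * mort_scale)
    qbg[ages[j] + tv >= config$horizon_age - 1L] <- 1
    for (ki in seq_len(6L)) {
      k <- STAGE_CODES[ki]
      excess <- if (k >= 0) {
        config$excess_hazard_by_stage[k + 1L] * pmax(0, 1 - tv / decay)
      } else 0
      haz <- pmin(1, qbg + excess)
      lam <- haz * cumprod(c(1, 1 - haz[-length(haz)]))
      survival[j, ki, seq_along(tv)] <- lam
      if (k >= 0) {
        share <- config$bc_death_share_by_stage[k + 1L] *
          pmax(0, 1 - tv / decay)
        causes[j, k + 1L, seq_along(tv), 1L] <- lam * share
        causes[j, k + 1L, seq_along(tv), 2L] <- lam * (1 - share)
      }
    }
  }

  out <- model_inputs(grid, incidence, stages, survival, causes,
                      paper_fixture()$cost_model, config$N0)
  bad <- validate_inputs(out)
  if (length(bad) > 0L) {
    stop("generator produced invalid inputs:\n  ",
         paste(bad, collapse = "\n  "))
  }
  out
}

#' Packaged reference constants: treatment-cost tables and the overall
#' stage distribution
#'
#' Loads the three packaged phase cost tables (7 age bands x 5 stages, in
#' euros: first year, yearly for years 2-5, last year before breast cancer
#' death) and the 30 euro per-invitee screening cost, together with the
#' overall diagnosed stage distribution (Unknown, Localized, Regional,
#' Distant/adjacent, In situ) of the Finnish registry material. The stage
#' vector is shipped exactly as published — it sums to 0.9995, not 1 — and
#' is a reference constant only, never used as a simplex input.
#'
#' @return list with \code{cost_model} (a \code{\link{cost_model}}) and
#'   \code{overall_stage_distribution} (length-5 numeric).
#' @export
paper_fixture <- function() {
  read_tab <- function(name) {
    f <- system.file("extdata", name, package = "flexscreen")
    if (f == "") f <- file.path("inst", "extdata", name) # pre-install use
    m <- as.matrix(utils::read.csv(f, check.names = FALSE)[, -1])
    storage.mode(m) <- "double"
    m
  }
  cm <- cost_model(read_tab("treatment_costs_year1.csv"),
                   read_tab("treatment_costs_years2_5.csv"),
                   read_tab("treatment_costs_final_year.csv"),
                   screening_unit_cost = 30)
  list(cost_model = cm,
       overall_stage_distribution = c(unknown = 0.096, localized = 0.522,
                                      regional = 0.254, distant = 0.0085,
                                      in_situ = 0.119))
}

#' Small three-group synthetic fixture for examples
#'
#' @param seed generator seed.
#' @return a validated \code{model_inputs} with \code{J = 3}.
#' @export
toy_inputs <- function(seed = 7L) {
  generate_inputs(generator_config(seed = seed, J = 3L))
}

#' Synthetic stand-in for a steady-state old-age incidence pattern
#'
#' The older-extension scenario needs replacement incidence rates for the
#' groups above the current screening ages (a decline pattern such as the
#' one observed in Sweden). No such curve is packaged; this helper derives
#' a plausible synthetic stand-in from the baseline inputs: the newly
#' screened groups take their screened incidence with a mild first-screen
#' uplift at the first group, and the following two groups carry the
#' post-screening deficit outward.
#'
#' @param inputs baseline \code{model_inputs}.
#' @param flip_groups groups flipped to screening by the scenario.
#' @param bump relative uplift at the first newly screened group.
#' @param deficit relative deficit for the two groups after the extension.
#' @return named numeric vector suitable for
#'   \code{\link{build_older_extension}}.
#' @export
synthetic_older_incidence <- function(inputs, flip_groups = c(13L, 14L),
                                      bump = 0.10, deficit = 0.12) {
  J <- inputs$grid$J
  out <- numeric(0)
  for (j in flip_groups) {
    v <- inputs$incidence[j, "S"]
    if (j == min(flip_groups)) v <- min(1, v * (1 + bump))
    out[as.character(j)] <- v
  }
  post <- setdiff(seq_len(J), seq_len(max(flip_groups)))
  post <- utils::head(post, 2L)
  fade <- c(1, 0.5)[seq_along(post)]
  for (i in seq_along(post)) {
    out[as.character(post[i])] <-
      inputs$incidence[post[i], "NS"] * (1 - deficit * fade[i])
  }
  out
}
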