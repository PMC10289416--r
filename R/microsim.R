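#' Individual-level Monte Carlo simulation of a screening cohort
#'
#' Independent stochastic replica of the closed-form cohort accounting,
#' used to validate \code{\link{total_life_years}},
#' \code{\link{total_costs}} and \code{\link{expected_bc_deaths}}. Each
#' individual walks the screening rounds: at round \code{j} her state is
#' drawn from \code{mu_{j,h}}; a diagnosed woman draws a survival time and
#' cause of death from \code{pi_{j,k}}, is credited the drawn \code{t}
#' years plus the accumulated treatment cost, and leaves; a cancer-free
#' woman draws \code{t} from \code{lam_{j,-1}}: dying within the interval
#' credits \code{t} years (0 or 1) and she leaves, otherwise she is
#' credited 2 years on reaching the next round. Surviving the final round
#' earns no further credit, mirroring the closed form, which stops its
#' year accounting at the horizon. Screening cost accrues per invited round
#' under a screened status, including the round of diagnosis or death.
#'
#' Draw order per round, within one RNG stream: state draws for all active
#' individuals, then survival/cause draws for diagnosed individuals by
#' ascending stage, then survival draws for cancer-free individuals.
#' Results are reproducible given \code{seed}.
#'
#' @param inputs a validated \code{model_inputs}.
#' @param policy policy vector.
#' @param n_individuals number of simulated individuals (>= 1).
#' @param seed integer RNG seed; recorded in the output.
#' @return an object of class \code{sim_result}: cohort-scaled estimates
#'   \code{ET}, \code{EC}, \code{bc_deaths} (each mean per individual times
#'   \code{N0}), their Monte Carlo standard errors \code{se_ET},
#'   \code{se_EC}, \code{se_bc_deaths}, plus \code{n}, \code{seed} and
#'   \code{N0}.
#' @export
simulate_cohort <- function(inputs, policy, n_individuals = 2e5, seed = 1L) {
  assert_valid(inputs)
  check_policy(policy, inputs$grid)
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  set.seed(seed)
  walks <- sim_walk(inputs, policy, n_individuals)
  scale <- inputs$N0
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  structure(list(ET = mean(walks$life_years) * scale,
                 EC = mean(walks$cost) * scale,
                 bc_deaths = mean(walks$died_of_bc) * scale,
                 se_ET = se(walks$life_years) * scale,
                 se_EC = se(walks$cost) * scale,
                 se_bc_deaths = se(walks$died_of_bc) * scale,
                 n = as.integer(n_individuals), seed = seed, N0 = scale),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(paste0("sim_result (n = %d, seed = %d):\n",
                     "  ET = %.1f (se %.1f)\n  EC = %.1f (se %.1f)\n",
                     "  BC deaths = %.2f (se %.2f)\n"),
              x$n, x$seed, x$ET, x$se_ET, x$EC, x$se_EC,
              x$bc_deaths, x$se_bc_deaths))
  invisible(x)
}

#' Simulate a single individual's screening history
#'
#' One walk of the process behind \code{\link{simulate_cohort}}.
#'
#' @inheritParams simulate_cohort
#' @return list with \code{life_years}, \code{cost}, \code{died_of_bc}.
#' @export
simulate_individual <- function(inputs, policy, seed = 1L) {
  assert_valid(inputs)
  check_policy(policy, inputs$grid)
  set.seed(seed)
  w <- sim_walk(inputs, policy, 1L)
  list(life_years = w$life_years, cost = w$cost,
       died_of_bc = as.logical(w$died_of_bc))
}

# Vectorised core: walks `n` individuals through all rounds. Assumes the
# RNG state has been set by the caller.
sim_walk <- function(inputs, policy, n) {
  grid <- inputs$grid
  J <- grid$J
  Tn <- dim(inputs$survival)[3]
  mu <- compose_state_distribution(inputs$incidence, inputs$stages, policy)
  bands <- band_of(seq_len(J), grid)
  unit <- inputs$cost_model$screening_unit_cost

  active <- rep(TRUE, n)
  years <- numeric(n)
  cost <- numeric(n)
  bc <- numeric(n)

  for (j in seq_len(J)) {
    idx <- which(active)
    if (length(idx) == 0L) break
    if (policy[j] == "S") cost[idx] <- cost[idx] + unit
    state <- sample.int(6L, length(idx), replace = TRUE, prob = mu[j, ]) - 2L
    for (k in 0:4) {
      who <- idx[state == k]
      if (length(who) == 0L) next
      pjk <- inputs$causes[j, k + 1L, , ] # Tn x 2
      cell <- sample.int(2L * Tn, length(who), replace = TRUE, prob = pjk)
      t_draw <- (cell - 1L) %% Tn
      d_draw <- (cell - 1L) %/% Tn + 1L
      years[who] <- years[who] + t_draw
      cost[who] <- cost[who] +
        accumulate_cost(t_draw + 1L, d_draw, bands[j], k, inputs$cost_model)
      bc[who] <- bc[who] + (d_draw == 1L)
      active[who] <- FALSE
    }
    free <- idx[state == -1L]
    if (length(free) > 0L) {
      t_draw <- sample.int(Tn, length(free), replace = TRUE,
                           prob = inputs$survival[j, 1L, ]) - 1L
      dies <- t_draw <= 1L
      years[free[dies]] <- years[free[dies]] + t_draw[dies]
      active[free[dies]] <- FALSE
      surv <- free[!dies]
      if (j < J) {
        years[surv] <- years[surv] + 2
      } else {
        active[surv] <- FALSE
      }
    }
  }
  list(life_years = years, cost = cost, died_of_bc = bc)
}

#' Compare analytic and simulated cohort summaries
#'
#' Runs the closed forms and the simulator on the same inputs and reports
#' the z-scores \code{(analytic - simulated) / SE} for expected life-years,
#' expected costs and expected breast cancer deaths.
#'
#' @inheritParams simulate_cohort
#' @return data.frame with one row per quantity: analytic value, simulated
#'   value, Monte Carlo SE and z-score.
#' @export
oracle_check <- function(inputs, policy, n_individuals = 2e5, seed = 1L) {
  res <- policy_result(inputs, policy)
  sim <- simulate_cohort(inputs, policy, n_individuals, seed)
  data.frame(
    quantity = c("ET", "EC", "bc_deaths"),
    analytic = c(res$ET, res$EC, res$bc_deaths),
    simulated = c(sim$ET, sim$EC, sim$bc_deaths),
    se = c(sim$se_ET, sim$se_EC, sim$se_bc_deaths),
    z = c((res$ET - sim$ET) / sim$se_ET,
          (res$EC - sim$EC) / sim$se_EC,
          (res$bc_deaths - sim$bc_deaths) / sim$se_bc_deaths),
    stringsAsFactors = FALSE)
}
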