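#' Marginal death-time law at one screening round
#'
#' Mixes the stage-specific survival laws over the state distribution:
#' \code{P(T_j = t) = sum_k lam(j, k, t) mu(j, k)} with \code{k} running
#' over \code{-1..4}.
#'
#' @param mu \code{J x 6} state distribution matrix (from
#'   \code{\link{compose_state_distribution}}).
#' @param survival \code{J x 6 x T} survival array.
#' @param j age-group index.
#' @return numeric vector over \code{t = 0..T-1}, summing to 1.
#' @export
marginal_death_law <- function(mu, survival, j) {
  if (j < 1 || j > nrow(mu) || j > dim(survival)[1]) {
    stop("no laws defined for age group j = ", j)
  }
  drop(mu[j, ] %*% survival[j, , ])
}

#' One step of the cohort recursion
#'
#' Invitees leave the cohort by dying within the 2-year interval or by
#' being diagnosed (and censored) while surviving to the next round:
#' \deqn{N_{j+1} = N_j (1 - P(T_j \in \{0,1\}) - P(T_j \ge 2, X_j \ne -1)).}
#'
#' @param N_j expected invitees at round \code{j} (real-valued).
#' @param mu state distribution matrix.
#' @param survival survival array.
#' @param j age-group index.
#' @return \code{N_{j+1}}, in \code{[0, N_j]}.
#' @export
advance_population <- function(N_j, mu, survival, j) {
  if (N_j < 0) stop("N_j must be non-negative")
  pT <- marginal_death_law(mu, survival, j)
  p_die_early <- sum(pT[1:2])
  # P(T_j >= 2, X != -1) = sum_{k>=0} mu(k) * P(T_{j,k} >= 2)
  p_live2_k <- rowSums(matrix(survival[j, -1L, -(1:2), drop = FALSE],
                              nrow = 5L))
  p_diag_live <- sum(mu[j, -1L] * p_live2_k)
  keep <- 1 - p_die_early - p_diag_live
  if (keep < -PROB_TOL) {
    stop("internal consistency error: negative retention probability at j = ", j)
  }
  N_j * max(keep, 0)
}

#' Expected cohort trajectory under a policy
#'
#' @param inputs a validated \code{model_inputs}.
#' @param h policy vector.
#' @param validate run \code{\link{validate_inputs}} first (default TRUE).
#' @return numeric vector \code{N_1..N_J}, non-increasing, with
#'   \code{N_1 = N0}.
#' @export
cohort_trajectory <- function(inputs, h, validate = TRUE) {
  if (validate) assert_valid(inputs)
  check_policy(h, inputs$grid)
  mu <- compose_state_distribution(inputs$incidence, inputs$stages, h)
  J <- inputs$grid$J
  N <- numeric(J)
  N[1] <- inputs$N0
  if (J > 1L) {
    for (j in seq_len(J - 1L)) {
      N[j + 1L] <- advance_population(N[j], mu, inputs$survival, j)
    }
  }
  N
}

#' Total expected life-years of the cohort under a policy
#'
#' Closed-form accounting: each arrival at rounds 2..J contributes the two
#' years just lived; at every round, cancer-free women dying within the
#' interval contribute \code{lam(j,-1)(1)} one year (a death at \code{t = 0}
#' contributes none), and diagnosed women are censored with their full
#' expected remaining years \code{E T_{j,k}}:
#' \deqn{E T_h = \sum_{j=2}^{J} 2 N_j + \sum_{j=1}^{J}
#'   \Big[\lambda_{j,-1}(1)\,\mu_{j,h}(-1)
#'   + \sum_{k=0}^{K} \mu_{j,h}(k)\, E T_{j,k}\Big] N_j.}
#' Survivors of the final round receive no further credit; the horizon ends
#' the accounting there.
#'
#' @inheritParams cohort_trajectory
#' @return list with \code{ET} (total expected life-years) and
#'   \code{trajectory} (the \code{N_j} vector).
#' @export
total_life_years <- function(inputs, h, validate = TRUE) {
  if (validate) assert_valid(inputs)
  check_policy(h, inputs$grid)
  N <- cohort_trajectory(inputs, h, validate = FALSE)
  mu <- compose_state_distribution(inputs$incidence, inputs$stages, h)
  J <- inputs$grid$J
  tv <- seq_len(dim(inputs$survival)[3]) - 1
  per_round <- numeric(J)
  for (j in seq_len(J)) {
    et_jk <- drop(inputs$survival[j, -1L, , drop = TRUE] %*% tv) # k = 0..4
    per_round[j] <- inputs$survival[j, 1L, 2L] * mu[j, 1L] +
      sum(mu[j, -1L] * et_jk)
  }
  ET <- sum(2 * N[-1L]) + sum(per_round * N)
  list(ET = ET, trajectory = N)
}

#' Total expected costs of the cohort under a policy
#'
#' Per age group, screening costs accrue for every invitee when the group
#' is screened, and treatment costs accrue for diagnosed women according to
#' the cost tensor weighted by the joint survival/cause law:
#' \deqn{E C_{j,h} = N_j \tilde C_h(j) + \sum_{k=0}^{K} N_j \mu_{j,h}(k)
#'   \sum_t \sum_d \tilde C_{j,k,t,d}\, \pi_{j,k}(t,d),}
#' \deqn{E C_h = \sum_j E C_{j,h}.}
#'
#' @inheritParams cohort_trajectory
#' @return list with \code{EC} (total), \code{per_age} (the
#'   \code{E C_{j,h}}), and the \code{screening} / \code{treatment}
#'   components of the total.
#' @export
total_costs <- function(inputs, h, validate = TRUE) {
  if (validate) assert_valid(inputs)
  check_policy(h, inputs$grid)
  grid <- inputs$grid
  N <- cohort_trajectory(inputs, h, validate = FALSE)
  mu <- compose_state_distribution(inputs$incidence, inputs$stages, h)
  Tn <- dim(inputs$survival)[3]
  ct <- build_cost_tensor(inputs$cost_model, grid, Tn)
  J <- grid$J
  screening <- numeric(J)
  treatment <- numeric(J)
  for (j in seq_len(J)) {
    screening[j] <- N[j] *
      (if (h[j] == "S") inputs$cost_model$screening_unit_cost else 0)
    exp_cost_k <- vapply(1:5, function(ki) {
      sum(ct[j, ki, , ] * inputs$causes[j, ki, , ])
    }, numeric(1))
    treatment[j] <- N[j] * sum(mu[j, -1L] * exp_cost_k)
  }
  per_age <- screening + treatment
  list(EC = sum(per_age), per_age = per_age,
       screening = sum(screening), treatment = sum(treatment))
}

#' Expected breast cancer deaths in the cohort under a policy
#'
#' \deqn{\sum_j N_j \sum_{k \ge 0} \mu_{j,h}(k) \sum_t \pi_{j,k}(t, d = 1).}
#' Only diagnosed women can die of breast cancer in this model.
#'
#' @inheritParams cohort_trajectory
#' @return expected number of breast cancer deaths (real-valued).
#' @export
expected_bc_deaths <- function(inputs, h, validate = TRUE) {
  if (validate) assert_valid(inputs)
  check_policy(h, inputs$grid)
  N <- cohort_trajectory(inputs, h, validate = FALSE)
  mu <- compose_state_distribution(inputs$incidence, inputs$stages, h)
  J <- inputs$grid$J
  deaths <- 0
  for (j in seq_len(J)) {
    p_bc_k <- rowSums(inputs$causes[j, , , 1, drop = TRUE])
    deaths <- deaths + N[j] * sum(mu[j, -1L] * p_bc_k)
  }
  deaths
}

#' Evaluate one policy end to end
#'
#' @inheritParams cohort_trajectory
#' @param label policy label used in comparison tables.
#' @return an object of class \code{policy_result} with fields \code{EC},
#'   \code{ET}, \code{ratio} (\code{EC/ET}), \code{bc_deaths},
#'   \code{trajectory}, \code{per_age_costs}, and the screening/treatment
#'   cost components.
#' @export
policy_result <- function(inputs, h, label = "policy", validate = TRUE) {
  if (validate) assert_valid(inputs)
  ly <- total_life_years(inputs, h, validate = FALSE)
  co <- total_costs(inputs, h, validate = FALSE)
  structure(list(label = label,
                 policy = h,
                 EC = co$EC,
                 ET = ly$ET,
                 ratio = if (ly$ET > 0) co$EC / ly$ET else NA_real_,
                 bc_deaths = expected_bc_deaths(inputs, h, validate = FALSE),
                 trajectory = ly$trajectory,
                 per_age_costs = co$per_age,
                 screening_cost = co$screening,
                 treatment_cost = co$treatment),
            class = "policy_result")
}

#' @export
print.policy_result <- function(x, ...) {
  cat(sprintf("policy_result '%s': EC = %.1f, ET = %.1f, EC/ET = %.2f, BC deaths = %.1f\n",
              x$label, x$EC, x$ET, x$ratio, x$bc_deaths))
  invisible(x)
}

#' Assemble a cost-effectiveness comparison table from policy results
#'
#' The first element is the reference policy; its incremental columns are
#' left empty. Incremental quantities use the convention alternative minus
#' reference, so \code{icer = (EC_h - EC_ref) / (ET_h - ET_ref)} euros per
#' life-year gained; the ICER is undefined (NA) when the life-year
#' difference is zero.
#'
#' @param results list of \code{policy_result}, reference first.
#' @return data.frame with columns \code{policy}, \code{EC}, \code{ET},
#'   \code{ratio}, \code{incremental_cost}, \code{icer}, \code{bc_deaths}.
#' @export
comparison_table <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "policy_result")))
  ref <- results[[1L]]
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (i == 1L) {
      dc <- NA_real_; ic <- NA_real_
    } else {
      dc <- r$EC - ref$EC
      dt <- r$ET - ref$ET
      ic <- if (dt == 0) NA_real_ else dc / dt
    }
    data.frame(policy = r$label, EC = r$EC, ET = r$ET, ratio = r$ratio,
               incremental_cost = dc, icer = ic, bc_deaths = r$bc_deaths,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare alternative policies against a reference on common inputs
#'
#' @param inputs a validated \code{model_inputs}.
#' @param reference reference policy vector.
#' @param alternatives list of alternative policy vectors.
#' @param labels optional labels (reference label first).
#' @return comparison data.frame (see \code{\link{comparison_table}}).
#' @export
compare_policies <- function(inputs, reference, alternatives,
                             labels = NULL) {
  assert_valid(inputs)
  policies <- c(list(reference), alternatives)
  if (is.null(labels)) {
    labels <- c("reference", paste0("alt", seq_along(alternatives)))
  }
  res <- Map(function(h, lab) policy_result(inputs, h, lab, validate = FALSE),
             policies, labels)
  comparison_table(res)
}
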