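#' Age grid for a biennial screening cohort
#'
#' The cohort is followed in 2-year age groups: group \code{j} covers ages
#' \code{44 + 2j} to \code{45 + 2j}, so \code{j = 1} is the 46-47 year old
#' women and \code{j = 27} the 98-99 year old women. No one survives past
#' \code{horizon_age}.
#'
#' @param J number of 2-year age groups (default 27, ages 46-99).
#' @param horizon_age absolute survival horizon in years (default 100).
#' @return an object of class \code{age_grid}.
#' @export
age_grid <- function(J = 27L, horizon_age = 100L) {
  J <- as.integer(J)
  if (J < 1L) stop("J must be >= 1")
  if (44L + 2L * J + 1L > horizon_age) {
    stop("age grid extends past horizon_age ", horizon_age)
  }
  structure(list(J = J, horizon_age = as.integer(horizon_age)),
            class = "age_grid")
}

#' @rdname age_grid
#' @param grid an \code{age_grid}.
#' @param j age-group index (vectorised).
#' @export
lower_age <- function(grid, j) 44L + 2L * as.integer(j)

#' @rdname age_grid
#' @export
t_max <- function(grid, j) grid$horizon_age - lower_age(grid, j)

#' @export
print.age_grid <- function(x, ...) {
  cat(sprintf("age_grid: %d biennial groups, ages %d-%d, horizon %d\n",
              x$J, lower_age(x, 1L), lower_age(x, x$J) + 1L, x$horizon_age))
  invisible(x)
}

STAGE_CODES <- -1:4
STAGE_LABELS <- c("k-1", "k0", "k1", "k2", "k3", "k4")
DIAG_STAGE_LABELS <- STAGE_LABELS[-1]
STATUS_LEVELS <- c("S", "NS")
PROB_TOL <- 1e-9

#' Screening policy vectors
#'
#' A policy assigns every age group to screening (\code{"S"}) or
#' no-screening (\code{"NS"}). \code{screening_policy()} builds the policy
#' that screens all groups whose ages fall inside \code{[from_age, to_age]};
#' \code{finnish_current_policy()} is the reference policy screening ages
#' 50-69.
#'
#' @param grid an \code{age_grid}.
#' @param from_age,to_age inclusive age range invited to screening.
#' @return character vector of length \code{J} over \code{c("S", "NS")}.
#' @export
screening_policy <- function(grid, from_age, to_age) {
  lo <- lower_age(grid, seq_len(grid$J))
  ifelse(lo >= from_age & lo + 1L <= to_age, "S", "NS")
}

#' @rdname screening_policy
#' @export
finnish_current_policy <- function(grid) screening_policy(grid, 50, 69)

check_policy <- function(h, grid) {
  if (length(h) != grid$J || !all(h %in% STATUS_LEVELS)) {
    stop("policy must be a length-", grid$J, " vector over {S, NS}")
  }
  invisible(h)
}

#' Bundle model parameters into a validated input object
#'
#' @param grid an \code{age_grid}.
#' @param incidence numeric matrix \code{J x 2} (columns \code{"S"},
#'   \code{"NS"}): probability that an invitee of age group \code{j} is
#'   diagnosed with breast cancer during the 2-year interval, by screening
#'   status.
#' @param stages numeric array \code{J x 2 x 5} (status, stages
#'   \code{k0..k4}): conditional stage distribution given diagnosis. Stage
#'   codes: 0 Unknown, 1 Localized, 2 Regional, 3 Distant/adjacent,
#'   4 In situ.
#' @param survival numeric array \code{J x 6 x T} (stages \code{k-1..k4},
#'   \code{t = 0..T-1}): \code{P(T_{j,k} = t)}, the probability of living
#'   exactly \code{t} whole years after observation at round \code{j} in
#'   state \code{k}; \code{k = -1} is the cancer-free background law.
#' @param causes numeric array \code{J x 5 x T x 2} (stages \code{k0..k4},
#'   causes \code{d = 1} breast cancer, \code{d = 2} other): joint law
#'   \code{P(T = t, D = d)}; its \code{d}-marginal must equal
#'   \code{survival} for every diagnosed stage.
#' @param cost_model a \code{\link{cost_model}}.
#' @param N0 initial cohort size (expected invitees at round 1);
#'   default 100000.
#' @return an object of class \code{model_inputs}.
#' @export
model_inputs <- function(grid, incidence, stages, survival, causes,
                         cost_model, N0 = 1e5) {
  x <- structure(list(grid = grid,
                      incidence = incidence,
                      stages = stages,
                      survival = survival,
                      causes = causes,
                      cost_model = cost_model,
                      N0 = N0),
                 class = "model_inputs")
  x
}

#' @export
print.model_inputs <- function(x, ...) {
  cat("model_inputs:\n")
  print(x$grid)
  cat(sprintf("  survival support t = 0..%d; N0 = %g\n",
              dim(x$survival)[3] - 1L, x$N0))
  nv <- length(validate_inputs(x))
  cat(sprintf("  validation: %s\n",
              if (nv == 0L) "OK" else paste(nv, "violation(s)")))
  invisible(x)
}

#' Validate model inputs
#'
#' Checks every structural invariant and returns a character vector of
#' violations (empty when the inputs are valid). Inputs are never repaired:
#' a conditional stage row summing to 0.98 is reported, not renormalised,
#' because silent repair would mask data-entry errors in parameter files.
#'
#' @param inputs a \code{model_inputs} object.
#' @param tol tolerance for probability sums (default \code{1e-9}).
#' @return character vector of violation messages; \code{character(0)} if
#'   valid.
#' @export
validate_inputs <- function(inputs, tol = PROB_TOL) {
  bad <- character(0)
  grid <- inputs$grid
  J <- grid$J

  inc <- inputs$incidence
  if (!is.matrix(inc) || nrow(inc) != J ||
      !all(STATUS_LEVELS %in% colnames(inc))) {
    return("incidence must be a J x 2 matrix with columns S, NS")
  }
  for (s in STATUS_LEVELS) {
    out <- which(inc[, s] < 0 | inc[, s] > 1)
    for (j in out) {
      bad <- c(bad, sprintf("incidence: iota(j=%d, %s) = %g outside [0,1]",
                            j, s, inc[j, s]))
    }
  }

  q <- inputs$stages
  if (length(dim(q)) != 3L || dim(q)[1] != J || dim(q)[3] != 5L) {
    return("stages must be a J x 2 x 5 array")
  }
  for (s in STATUS_LEVELS) {
    for (j in seq_len(J)) {
      row <- q[j, s, ]
      if (any(row < 0)) {
        bad <- c(bad, sprintf("stages: q(j=%d, %s) has negative entries", j, s))
      }
      if (abs(sum(row) - 1) > tol) {
        bad <- c(bad, sprintf(
          "stages: q(j=%d, %s) sums to %.12g, not 1", j, s, sum(row)))
      }
    }
  }

  lam <- inputs$survival
  if (length(dim(lam)) != 3L || dim(lam)[1] != J || dim(lam)[2] != 6L) {
    return("survival must be a J x 6 x T array (stages k-1..k4)")
  }
  Tn <- dim(lam)[3]
  tv <- seq_len(Tn) - 1L
  for (j in seq_len(J)) {
    tm <- t_max(grid, j)
    for (ki in seq_len(6L)) {
      row <- lam[j, ki, ]
      k <- STAGE_CODES[ki]
      if (any(row < 0)) {
        bad <- c(bad, sprintf("survival: lam(j=%d, k=%d) has negative mass", j, k))
      }
      if (abs(sum(row) - 1) > tol) {
        bad <- c(bad, sprintf(
          "survival: lam(j=%d, k=%d) sums to %.12g, not 1", j, k, sum(row)))
      }
      if (any(row[tv > tm] > tol)) {
        bad <- c(bad, sprintf(
          "survival: lam(j=%d, k=%d) has mass beyond t_max = %d (horizon %d)",
          j, k, tm, grid$horizon_age))
      }
    }
  }

  pi <- inputs$causes
  if (length(dim(pi)) != 4L || dim(pi)[1] != J || dim(pi)[2] != 5L ||
      dim(pi)[3] != Tn || dim(pi)[4] != 2L) {
    return("causes must be a J x 5 x T x 2 array aligned with survival")
  }
  if (any(pi < 0)) bad <- c(bad, "causes: pi has negative entries")
  for (j in seq_len(J)) {
    for (ki in seq_len(5L)) {
      marg <- pi[j, ki, , 1] + pi[j, ki, , 2]
      off <- which(abs(marg - lam[j, ki + 1L, ]) > tol)
      if (length(off) > 0L) {
        bad <- c(bad, sprintf(
          "causes: sum_d pi(j=%d, k=%d, t=%d, d) != lam (marginal constraint)",
          j, STAGE_CODES[ki + 1L], off[1] - 1L))
      }
    }
  }

  bad <- c(bad, validate_cost_model(inputs$cost_model))
  if (!is.numeric(inputs$N0) || inputs$N0 <= 0) {
    bad <- c(bad, sprintf("N0 = %g must be positive", inputs$N0))
  }
  bad
}

assert_valid <- function(inputs, tol = PROB_TOL) {
  bad <- validate_inputs(inputs, tol)
  if (length(bad) > 0L) {
    stop("invalid model inputs:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(inputs)
}

#' Compose incidence and conditional stage distributions into state
#' distributions
#'
#' The state of an invitee at round \code{j} is \code{k = -1} (no breast
#' cancer) or a diagnosed stage \code{k = 0..4}. Incidence and the
#' conditional stage law factorise the state distribution:
#' \code{mu(j, k) = q(j, h(j), k) * iota(j, h(j))} for \code{k >= 0} and
#' \code{mu(j, -1) = 1 - iota(j, h(j))}.
#'
#' @param incidence \code{J x 2} incidence matrix (see
#'   \code{\link{model_inputs}}).
#' @param stages \code{J x 2 x 5} conditional stage array.
#' @param h policy vector over \code{c("S", "NS")}.
#' @param tol probability-sum tolerance.
#' @return a \code{J x 6} matrix with columns \code{k-1, k0, ..., k4}; each
#'   row sums to 1.
#' @export
compose_state_distribution <- function(incidence, stages, h,
                                       tol = PROB_TOL) {
  J <- nrow(incidence)
  if (length(h) != J || !all(h %in% STATUS_LEVELS)) {
    stop("policy must have length ", J, " over {S, NS}")
  }
  mu <- matrix(0, J, 6L, dimnames = list(NULL, STAGE_LABELS))
  for (j in seq_len(J)) {
    iota <- incidence[j, h[j]]
    if (is.na(iota) || iota < 0 || iota > 1) {
      stop(sprintf("iota(j=%d, %s) = %g outside [0,1]", j, h[j], iota))
    }
    qrow <- stages[j, h[j], ]
    if (any(qrow < 0) || abs(sum(qrow) - 1) > tol) {
      stop(sprintf("stage row q(j=%d, %s) is not a distribution (sum %.12g)",
                   j, h[j], sum(qrow)))
    }
    mu[j, 1L] <- 1 - iota
    mu[j, -1L] <- qrow * iota
  }
  mu
}

#' Decompose a state distribution back into incidence and conditional
#' stage probabilities
#'
#' Inverse of \code{\link{compose_state_distribution}} for one age group;
#' defined when the diagnosis probability is positive.
#'
#' @param mu_row length-6 state probability vector (\code{k = -1..4}).
#' @return list with \code{iota} and the length-5 conditional vector
#'   \code{q}.
#' @export
decompose_state_distribution <- function(mu_row) {
  iota <- 1 - mu_row[1L]
  if (iota <= 0) stop("cannot decompose: diagnosis probability is 0")
  list(iota = unname(iota), q = unname(mu_row[-1L] / iota))
}

#' Expected remaining whole years under a discrete survival law
#'
#' For the per-(age group, stage) survival mass \code{lam(t) = P(T = t)},
#' returns \code{E T = sum_t t * lam(t)}.
#'
#' @param lam_row numeric vector of probabilities over \code{t = 0, 1, ...}.
#' @param tol tolerance on the normalisation check.
#' @return expected number of whole years, a non-negative scalar.
#' @export
expected_remaining_years <- function(lam_row, tol = PROB_TOL) {
  if (any(lam_row < 0) || abs(sum(lam_row) - 1) > tol) {
    stop("survival mass is not a probability distribution (sum ",
         format(sum(lam_row), digits = 12), ")")
  }
  sum((seq_along(lam_row) - 1) * lam_row)
}
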