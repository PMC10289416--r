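test_that("marginal death law is the stage mixture of survival laws", {
  J <- 2L
  # single component: no cancer
  fix <- make_fixture(J, iota_S = 0, iota_NS = 0,
                      lam_free = c(0.2, 0.3, 0.1, 0.4), Tn = 4L)
  mu <- compose_state_distribution(fix$incidence, fix$stages, all_NS(J))
  expect_equal(marginal_death_law(mu, fix$survival, 1L),
               c(0.2, 0.3, 0.1, 0.4))

  # equal-weight point masses at t = 1 and t = 3
  fix2 <- make_fixture(J, iota_S = 0.5, iota_NS = 0.5,
                       q = c(0, 1, 0, 0, 0),
                       lam_free = c(0, 1, 0, 0),
                       lam_diag = c(0, 0, 0, 1), Tn = 4L)
  mu2 <- compose_state_distribution(fix2$incidence, fix2$stages, all_S(J))
  expect_equal(marginal_death_law(mu2, fix2$survival, 1L),
               c(0, 0.5, 0, 0.5))

  # arbitrary generated fixture: equals brute-force mixture summation
  inp <- generate_inputs(generator_config(seed = 9, J = 4L))
  mug <- compose_state_distribution(inp$incidence, inp$stages, all_S(4L))
  for (j in 1:4) {
    got <- marginal_death_law(mug, inp$survival, j)
    want <- numeric(dim(inp$survival)[3])
    for (ki in 1:6) want <- want + mug[j, ki] * inp$survival[j, ki, ]
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
  expect_error(marginal_death_law(mug, inp$survival, 9L), "j = 9")
})

test_that("population recursion removes deaths and diagnosed survivors", {
  J <- 2L
  # nobody leaves: no cancer, everyone survives two years
  fix <- make_fixture(J, iota_S = 0, iota_NS = 0)
  mu <- compose_state_distribution(fix$incidence, fix$stages, all_NS(J))
  expect_equal(advance_population(1000, mu, fix$survival, 1L), 1000)

  # 10% of cancer-free women die within the interval
  fix2 <- make_fixture(J, iota_S = 0, iota_NS = 0,
                       lam_free = c(0.04, 0.06, 0, 0.9), Tn = 4L)
  mu2 <- compose_state_distribution(fix2$incidence, fix2$stages, all_NS(J))
  expect_equal(advance_population(1000, mu2, fix2$survival, 1L), 900)

  # censoring at diagnosis only: all survive, 1% diagnosed
  fix3 <- make_fixture(J, iota_S = 0.01, iota_NS = 0.01)
  mu3 <- compose_state_distribution(fix3$incidence, fix3$stages, all_S(J))
  expect_equal(advance_population(1000, mu3, fix3$survival, 1L), 990)
  expect_error(advance_population(-1, mu3, fix3$survival, 1L),
               "non-negative")
})

test_that("life-year accounting matches the closed form's edge cases", {
  # J = 1, no cancer, everyone lives exactly one year
  fix <- make_fixture(1L, iota_S = 0, iota_NS = 0,
                      lam_free = c(0, 1, 0, 0), Tn = 4L)
  expect_equal(total_life_years(fix, all_NS(1L))$ET, fix$N0)

  # J = 2, no cancer, everyone survives two years at every round:
  # only the inter-round credits contribute, and N_2 = N_0
  fix2 <- make_fixture(2L, iota_S = 0, iota_NS = 0)
  ly <- total_life_years(fix2, all_NS(2L))
  expect_equal(ly$trajectory, c(fix2$N0, fix2$N0))
  expect_equal(ly$ET, 2 * fix2$N0)
})

test_that("life years and trajectory agree with an independent recursion", {
  # dynamic-programming oracle over the same process, per individual
  dp_et <- function(inp, h) {
    mu <- compose_state_distribution(inp$incidence, inp$stages, h)
    J <- inp$grid$J
    tv <- 0:(dim(inp$survival)[3] - 1L)
    f <- 0
    for (j in J:1) {
      et_k <- vapply(1:5, function(ki) sum(tv * inp$survival[j, ki + 1, ]),
                     numeric(1))
      lam_free <- inp$survival[j, 1, ]
      p_surv <- sum(lam_free[tv >= 2])
      f <- sum(mu[j, -1] * et_k) +
        mu[j, 1] * (lam_free[2] + p_surv * ((j < J) * 2 + f))
    }
    unname(f * inp$N0)
  }
  for (seed in c(2, 4, 8)) {
    inp <- generate_inputs(generator_config(seed = seed, J = 5L))
    for (h in list(all_NS(5L), screening_policy(inp$grid, 50, 69))) {
      expect_equal(total_life_years(inp, h)$ET, dp_et(inp, h),
                   tolerance = 1e-10)
    }
  }
})

test_that("cost accounting separates screening and treatment exactly", {
  J <- 3L
  # no incidence, no screening: zero cost
  fix <- make_fixture(J, iota_S = 0, iota_NS = 0)
  fix$cost_model <- paper_costs
  expect_equal(total_costs(fix, all_NS(J))$EC, 0)

  # no incidence, screening everywhere: 30 euros per invitee per round
  co <- total_costs(fix, all_S(J))
  N <- cohort_trajectory(fix, all_S(J))
  expect_equal(co$EC, sum(30 * N))
  expect_equal(co$screening, co$EC)
  expect_equal(co$treatment, 0)
  expect_equal(co$per_age, 30 * N)
})

test_that("expected breast cancer deaths follow the cause-of-death law", {
  # nobody dies of breast cancer
  fix <- make_fixture(2L, bc_share = 0)
  expect_equal(expected_bc_deaths(fix, all_S(2L)), 0)

  # single group, 1% diagnosed, every diagnosed woman dies of breast cancer
  fix2 <- make_fixture(1L, iota_S = 0.01, iota_NS = 0.01, bc_share = 1)
  expect_equal(expected_bc_deaths(fix2, all_S(1L)), 0.01 * fix2$N0)
})

test_that("policy comparison computes incremental costs and ICER", {
  J <- 2L
  fix <- make_fixture(J, iota_S = 0, iota_NS = 0)
  # identical alternative: zero incremental cost, undefined ICER
  tab0 <- compare_policies(fix, all_NS(J), list(all_NS(J)))
  expect_true(is.na(tab0$incremental_cost[1]) && is.na(tab0$icer[1]))
  expect_equal(tab0$incremental_cost[2], 0)
  expect_true(is.na(tab0$icer[2]))

  # cost-only change: screening added where nothing is detected
  tab1 <- compare_policies(fix, all_NS(J), list(all_S(J)))
  N <- cohort_trajectory(fix, all_S(J))
  expect_equal(tab1$incremental_cost[2], sum(30 * N))
  expect_equal(tab1$ET[1], tab1$ET[2])
  expect_true(is.na(tab1$icer[2]))

  # hand-computed ICER on a two-policy toy: screening doubles detection,
  # diagnosed women die immediately, treatment is free
  toy <- make_fixture(2L, iota_S = 0.02, iota_NS = 0.01,
                      q = c(0, 1, 0, 0, 0),
                      lam_diag = c(1, 0, 0, 0, 0, 0))
  tab2 <- compare_policies(toy, all_NS(2L), list(all_S(2L)))
  # by hand: ET_h = 2 * N_2 = 2 * N0 * (1 - iota); EC_S = 30 * (N0 + N_2)
  et_ns <- 2 * 1e5 * 0.99
  et_s <- 2 * 1e5 * 0.98
  ec_s <- 30 * (1e5 + 1e5 * 0.98)
  expect_equal(tab2$ET, c(et_ns, et_s))
  expect_equal(tab2$EC, c(0, ec_s))
  expect_equal(tab2$icer[2], (ec_s - 0) / (et_s - et_ns))
})

test_that("trajectories shrink, costs scale linearly, ET is bounded", {
  for (seed in 1:4) {
    inp <- generate_inputs(generator_config(seed = seed, J = 6L))
    h <- screening_policy(inp$grid, 50, 69)
    N <- cohort_trajectory(inp, h)
    expect_true(all(diff(N) <= 1e-9))
    expect_true(all(N >= 0))

    co <- total_costs(inp, h)
    for (a in c(1.1, 1.5)) {
      scaled <- inp
      scaled$cost_model <- scale_treatment_costs(inp$cost_model, a)
      expect_equal(total_costs(scaled, h)$EC,
                   co$screening + a * co$treatment, tolerance = 1e-9)
    }

    ly <- total_life_years(inp, h)
    expect_lte(ly$ET,
               inp$N0 * (2 * inp$grid$J + dim(inp$survival)[3] - 1))
  }
})

test_that("ET never decreases when every survival law improves", {
  inp <- generate_inputs(generator_config(seed = 12, J = 5L))
  h <- screening_policy(inp$grid, 50, 69)
  base_et <- total_life_years(inp, h)$ET
  # first-order dominance shift: move 10% of the t=0 mass of every law to
  # t=1, and 10% of the cancer-free t=1 mass to t=2; the moved cause mass
  # is reassigned consistently so the joint law stays aligned
  imp <- inp
  for (j in 1:5) {
    for (ki in 1:6) {
      eps <- 0.1 * imp$survival[j, ki, 1]
      imp$survival[j, ki, 1] <- imp$survival[j, ki, 1] - eps
      imp$survival[j, ki, 2] <- imp$survival[j, ki, 2] + eps
      if (ki > 1) {
        sc <- imp$causes[j, ki - 1, 1, ]
        move <- if (sum(sc) > 0) eps * sc / sum(sc) else c(0, eps)
        imp$causes[j, ki - 1, 1, ] <- sc - move
        imp$causes[j, ki - 1, 2, ] <- imp$causes[j, ki - 1, 2, ] + move
      }
    }
    eps2 <- 0.1 * imp$survival[j, 1, 2]
    imp$survival[j, 1, 2] <- imp$survival[j, 1, 2] - eps2
    imp$survival[j, 1, 3] <- imp$survival[j, 1, 3] + eps2
  }
  expect_identical(validate_inputs(imp), character(0))
  expect_gte(total_life_years(imp, h)$ET, base_et)
})
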