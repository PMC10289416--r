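baseline27 <- generate_inputs(generator_config(seed = 21, J = 27L))

test_that("younger extension applies the documented adjustments exactly", {
  base <- baseline27
  h0 <- finnish_current_policy(base$grid)
  snapshot <- unserialize(serialize(base, NULL))
  young <- build_younger_extension(base)

  # builder is pure
  expect_identical(serialize(base, NULL), serialize(snapshot, NULL))

  # policy flips 46-47 and 48-49 to screening
  expect_equal(young$policy[1:2], c("S", "S"))
  expect_equal(young$policy[-(1:2)], h0[-(1:2)])

  # incidence adjustments: +28%, +24.7%, -11.9%, applied to the rate each
  # group had under the current policy
  expect_equal(unname(young$inputs$incidence[1, "S"] /
                        base$incidence[1, "NS"]), 1.28)
  expect_equal(unname(young$inputs$incidence[2, "S"] /
                        base$incidence[2, "NS"]), 1.247)
  expect_equal(unname(young$inputs$incidence[3, "S"] /
                        base$incidence[3, "S"]), 0.881)

  # stage substitutions are exact copies from the screened sources
  expect_identical(young$inputs$stages[1, "S", ], base$stages[3, "S", ])
  expect_identical(young$inputs$stages[2, "S", ], base$stages[4, "S", ])
  expect_identical(young$inputs$stages[3, "S", ], base$stages[4, "S", ])

  expect_identical(validate_inputs(young$inputs), character(0))
  expect_error(build_younger_extension(toy_inputs()), "J >= 4")
})

test_that("older extension shifts the old-age stage profile outward", {
  base <- baseline27
  ov <- synthetic_older_incidence(base)
  old <- build_older_extension(base, ov)

  expect_equal(old$policy[13:14], c("S", "S"))
  expect_equal(old$policy[15:27], rep("NS", 13))

  # newly screened groups take the oldest screened group's distribution
  expect_identical(old$inputs$stages[13, "S", ], base$stages[12, "S", ])
  expect_identical(old$inputs$stages[14, "S", ], base$stages[12, "S", ])
  # groups beyond the extension inherit the profile two groups younger
  expect_identical(old$inputs$stages[15, "NS", ], base$stages[13, "NS", ])
  expect_identical(old$inputs$stages[20, "NS", ], base$stages[18, "NS", ])

  # overrides land on the scenario statuses
  expect_equal(unname(old$inputs$incidence[13, "S"]), unname(ov[["13"]]))
  expect_equal(unname(old$inputs$incidence[15, "NS"]), unname(ov[["15"]]))

  # identity call returns the baseline untouched
  ident <- build_older_extension(base, NULL, flip_groups = integer(0))
  expect_identical(ident$inputs, base)
  expect_identical(ident$policy, finnish_current_policy(base$grid))

  # overrides must cover every newly screened group
  expect_error(build_older_extension(base, ov[1]), "cover every")
})

test_that("double extension composes the two builders on disjoint ranges", {
  base <- baseline27
  ov <- synthetic_older_incidence(base)
  both <- build_both_extension(base, ov)
  young <- build_younger_extension(base)
  old <- build_older_extension(base, ov)

  expect_equal(both$policy[1:14], rep("S", 14))
  expect_equal(both$policy[15:27], rep("NS", 13))

  # younger-side adjustments survive the composition
  expect_equal(unname(both$inputs$incidence[1, "S"] /
                        base$incidence[1, "NS"]), 1.28)
  # older-side substitutions identical to the older-only scenario
  expect_identical(both$inputs$stages[13, "S", ], old$inputs$stages[13, "S", ])
  expect_identical(both$inputs$stages[20, "NS", ],
                   old$inputs$stages[20, "NS", ])
  # the two touched ranges are disjoint, so each side matches its builder
  expect_identical(both$inputs$stages[1:3, , ], young$inputs$stages[1:3, , ])
  expect_identical(both$inputs$stages[13:27, , ],
                   old$inputs$stages[13:27, , ])
})

test_that("sensitivity transformations change exactly one dimension", {
  base <- generate_inputs(generator_config(seed = 6, J = 6L))

  up <- apply_sensitivity(base, "costs_up_50")
  expect_equal(up$cost_model$C1, base$cost_model$C1 * 1.5)
  expect_equal(up$cost_model$screening_unit_cost,
               base$cost_model$screening_unit_cost)
  expect_identical(up$incidence, base$incidence)
  expect_identical(up$stages, base$stages)

  # +10% and -10% are independent scenarios, not inverses
  inc_up <- apply_sensitivity(base, "incidence_up", groups = 1:6)
  inc_dn <- apply_sensitivity(inc_up, "incidence_down", groups = 1:6)
  expect_false(isTRUE(all.equal(inc_dn$incidence, base$incidence)))

  sh <- apply_sensitivity(base, "stage_up", groups = 1L)
  expect_equal(sh$stages[1, "S", "k1"], base$stages[1, "S", "k1"] + 0.02)
  expect_equal(sh$stages[1, "S", "k2"], base$stages[1, "S", "k2"] - 0.02)
  expect_identical(sh$stages[2:6, , ], base$stages[2:6, , ])
  expect_identical(validate_inputs(sh), character(0))

  # a shift that empties the regional stage is refused
  squeezed <- base
  squeezed$stages[, , "k2"] <- squeezed$stages[, , "k2"] +
    squeezed$stages[, , "k1"] - 0.01
  squeezed$stages[, , "k1"] <- 0.01
  expect_error(apply_sensitivity(squeezed, "stage_down", groups = 1:6),
               "negative conditional probability")
})

test_that("identity scenario reproduces the baseline result bit-exactly", {
  base <- generate_inputs(generator_config(seed = 14, J = 6L))
  h <- screening_policy(base$grid, 50, 69)
  spec <- scenario_spec("identity", policy = h)
  out <- apply_scenario(base, spec, baseline_policy = h)
  r0 <- policy_result(base, h)
  r1 <- policy_result(out$inputs, out$policy)
  expect_identical(r1$EC, r0$EC)
  expect_identical(r1$ET, r0$ET)
  expect_identical(r1$bc_deaths, r0$bc_deaths)
})

test_that("favourable stage shifts never lose life-years when localized
           disease survives longer than regional", {
  for (seed in c(3, 11, 19)) {
    base <- generate_inputs(generator_config(seed = seed, J = 6L))
    h <- screening_policy(base$grid, 50, 69)
    groups <- 1:6
    tv <- 0:(dim(base$survival)[3] - 1)
    dominance <- all(vapply(groups, function(j) {
      sum(tv * base$survival[j, "k1", ]) >= sum(tv * base$survival[j, "k2", ])
    }, logical(1)))
    expect_true(dominance) # generator builds localized-favourable survival
    et_up <- total_life_years(
      apply_sensitivity(base, "stage_up", groups = groups), h)$ET
    et_dn <- total_life_years(
      apply_sensitivity(base, "stage_down", groups = groups), h)$ET
    expect_gte(et_up, et_dn)
  }
})
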