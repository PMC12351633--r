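test_that("a candidate set within the cap degenerates to one exact solve", {
  s <- one_spherical_subject(seed = 31)
  labs <- s$leadfield$electrode_labels[1:6]
  cfg <- optimization_config(ga_population = 20, seed = 2)
  res <- ga_optimize(s, candidates = labs, config = cfg)
  ref <- solve_currents(labs, s, cfg)
  expect_equal(res$objective, ref$objective, tolerance = 1e-12)
  expect_equal(res$montage$currents, ref$currents, tolerance = 1e-12)
  expect_identical(res$generations_run, 0L)
})

test_that("the GA is deterministic for a fixed seed", {
  s <- one_spherical_subject(seed = 32)
  cfg <- optimization_config(ga_population = 40, max_electrodes = 3, seed = 9)
  r1 <- ga_optimize(s, config = cfg)
  r2 <- ga_optimize(s, config = cfg)
  expect_identical(r1$montage$currents, r2$montage$currents)
  expect_identical(r1$history, r2$history)
  r3 <- ga_optimize(s, config = optimization_config(
    ga_population = 40, max_electrodes = 3, seed = 10))
  expect_s3_class(r3, "optimization_result")  # different seed still valid
})

test_that("GA attains the exhaustive-subset optimum at small scale", {
  s <- one_spherical_subject(seed = 33)
  cands <- s$leadfield$electrode_labels[seq(1, 38, by = 2)][1:12]
  cfg0 <- optimization_config(max_electrodes = 3)
  subs <- utils::combn(cands, 3, simplify = FALSE)
  exact <- max(vapply(subs, function(ss)
    solve_currents(ss, s, cfg0)$objective, 0))
  hits <- 0L
  for (seed in 1:5) {
    cfg <- optimization_config(ga_population = 60, max_electrodes = 3,
                               seed = seed)
    res <- ga_optimize(s, candidates = cands, config = cfg)
    expect_lte(res$objective, exact + 1e-9)
    if (res$objective >= exact - 1e-6) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("GA history is non-decreasing and the result passes validation", {
  coh <- small_cohort(3, seed = 41)
  cfg <- optimization_config(ga_population = 50, seed = 4)
  res <- ga_optimize(coh, config = cfg)
  expect_true(all(diff(res$history) >= 0))
  expect_true(validate_montage(res$montage, cfg))
  expect_lte(length(res$active_electrodes), cfg$max_electrodes)
  expect_gte(res$objective, 0)
  g <- generics::glance(res)
  expect_lte(g$anodal_sum_mA, 4 + 1e-6)
})

test_that("small candidate sets are rejected", {
  s <- one_spherical_subject(seed = 31)
  expect_error(ga_optimize(s, candidates = "F3"), "at least 2")
})

test_that("leave-one-out on identical subjects reproduces the in-group fit", {
  coh <- small_cohort(2, seed = 51, radius_jitter = 0)
  cfg <- optimization_config(ga_population = 30, max_electrodes = 3, seed = 1)
  loo <- optimize_group_loo(coh, config = cfg)
  for (nm in names(loo)) {
    # the held-out subject is a copy of the training subject, so the
    # held-out NERNI equals the reported in-group objective
    expect_equal(loo[[nm]]$held_out$nerni, loo[[nm]]$objective,
                 tolerance = 1e-9)
  }
})

test_that("personalized optima dominate held-out group montages", {
  coh <- small_cohort(4, seed = 52)
  cfg <- optimization_config(ga_population = 50, max_electrodes = 3, seed = 3)
  loo <- optimize_group_loo(coh, config = cfg)
  for (i in seq_along(coh)) {
    cfg_i <- cfg; cfg_i$seed <- cfg$seed + 100 + i
    pers <- ga_optimize(coh[[i]], config = cfg_i)
    expect_gte(pers$objective + 1e-6,
               loo[[coh[[i]]$subject_id]]$held_out$nerni)
  }
})
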