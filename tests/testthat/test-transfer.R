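make_transfer_fixture <- function(n = 4, seed = 61) {
  coh <- small_cohort(n, seed = seed)
  cfg <- optimization_config(ga_population = 40, max_electrodes = 3,
                             seed = 1)
  pers <- list()
  for (i in seq_along(coh)) {
    cfg_i <- cfg; cfg_i$seed <- cfg$seed + i
    pers[[coh[[i]]$subject_id]] <- ga_optimize(coh[[i]], config = cfg_i)
  }
  list(cohort = coh, personalized = pers, config = cfg)
}

fx <- make_transfer_fixture()

test_that("a personalized montage scores its optimizer objective at home", {
  prot <- protocol_set(personalized = fx$personalized)
  tab <- evaluate_transfer(prot, fx$cohort)
  for (i in seq_along(fx$cohort)) {
    sid <- fx$cohort[[i]]$subject_id
    row <- tab[tab$subject_id == sid, ]
    expect_equal(nrow(row), 1L)   # own subject only
    expect_equal(row$nerni, fx$personalized[[sid]]$objective,
                 tolerance = 1e-9)
  }
})

test_that("a zero-current protocol scores zero everywhere", {
  prot <- protocol_set(templates = list(off = montage(c(F3 = 0))))
  tab <- evaluate_transfer(prot, fx$cohort)
  expect_equal(tab$nerni, rep(0, length(fx$cohort)))
  expect_equal(tab$mean_en, rep(0, length(fx$cohort)))
})

test_that("identical subjects receive identical transfer scores", {
  coh0 <- small_cohort(3, seed = 62, radius_jitter = 0)
  m <- random_montage(coh0[[1]], seed = 5)
  tab <- evaluate_transfer(list(shared = m), coh0)
  expect_lt(diff(range(tab$nerni)), 1e-12)
  expect_lt(diff(range(tab$mean_en)), 1e-12)
})

test_that("the transfer table is invariant to cohort ordering", {
  m <- random_montage(fx$cohort[[1]], seed = 6)
  t1 <- evaluate_transfer(list(p = m), fx$cohort)
  t2 <- evaluate_transfer(list(p = m), rev(fx$cohort))
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})

test_that("label mismatches are flagged per pair, not fatal", {
  bad <- montage(c(NOPE = 1))
  tab <- evaluate_transfer(list(bad = bad, off = montage(c(F3 = 0))),
                           fx$cohort)
  expect_true(all(is.na(tab$nerni[tab$protocol_id == "bad"])))
  expect_true(all(!is.na(tab$error[tab$protocol_id == "bad"])))
  expect_true(all(is.na(tab$error[tab$protocol_id == "off"])))
})

test_that("identical conditions give t = 0, p = 1; Bonferroni multiplies", {
  subj <- sprintf("s%02d", 1:8)
  set.seed(7)
  v <- rnorm(8)
  tab <- dplyr::bind_rows(
    tibble::tibble(subject_id = subj, protocol_id = "A",
                   protocol_kind = "template", nerni = v,
                   mean_en = v, error = NA_character_),
    tibble::tibble(subject_id = subj, protocol_id = "B",
                   protocol_kind = "template", nerni = v,
                   mean_en = v, error = NA_character_),
    tibble::tibble(subject_id = subj, protocol_id = "C",
                   protocol_kind = "template", nerni = v + rnorm(8, 0.5),
                   mean_en = v, error = NA_character_))
  cmp <- compare_protocols(tab)
  ab <- cmp$paired_tests[cmp$paired_tests$condition_a == "A" &
                           cmp$paired_tests$condition_b == "B", ]
  expect_equal(ab$t_statistic, 0)
  expect_equal(ab$p_value, 1)
  # three conditions -> three pairs -> Bonferroni factor 3
  expect_equal(cmp$paired_tests$p_adjusted,
               pmin(1, cmp$paired_tests$p_value * 3))
  expect_true(all(cmp$dunn$p_adjusted >= cmp$dunn$p_value - 1e-15))
  expect_true(all(cmp$dunn$p_adjusted <= 1))
})

test_that("paired t statistics match a hand-rolled oracle", {
  set.seed(8)
  subj <- sprintf("s%02d", 1:12)
  tab <- dplyr::bind_rows(lapply(c("A", "B", "C"), function(p)
    tibble::tibble(subject_id = subj, protocol_id = p,
                   protocol_kind = "template", nerni = rnorm(12),
                   mean_en = rnorm(12), error = NA_character_)))
  cmp <- compare_protocols(tab)
  wide <- tidyr::pivot_wider(tab[c("subject_id", "protocol_id", "nerni")],
                             names_from = "protocol_id",
                             values_from = "nerni")
  for (j in seq_len(nrow(cmp$paired_tests))) {
    a <- wide[[cmp$paired_tests$condition_a[j]]]
    b <- wide[[cmp$paired_tests$condition_b[j]]]
    d <- a - b
    t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
    expect_equal(cmp$paired_tests$t_statistic[j], t_hand,
                 tolerance = 1e-10)
  }
})

test_that("missing cells for paired tests are reported", {
  tab <- tibble::tibble(
    subject_id = c("s1", "s2", "s3", "s1", "s2"),
    protocol_id = c("A", "A", "A", "B", "B"),
    protocol_kind = "template",
    nerni = rnorm(5), mean_en = rnorm(5), error = NA_character_)
  expect_error(compare_protocols(tab), "incomplete")
})

test_that("paired-t power matches the closed-form prediction", {
  n <- 54; delta <- 0.02; sigma <- 0.05
  analytic <- stats::power.t.test(n = n, delta = delta, sd = sigma,
                                  type = "paired")$power
  set.seed(9)
  reps <- 400
  hits <- 0L
  for (r in seq_len(reps)) {
    d <- rnorm(n, delta, sigma)
    if (stats::t.test(d)$p.value < 0.05) hits <- hits + 1L
  }
  mc <- hits / reps
  se <- sqrt(analytic * (1 - analytic) / reps)
  expect_lt(abs(mc - analytic), 4 * se + 1e-3)
})

test_that("the quadratic NERNI vs mean-En fit recovers known structure", {
  # exact parabola
  x <- seq(0.01, 0.3, length.out = 40)
  tab <- tibble::tibble(nerni = 0.05 + 6 * x - 80 * x^2, mean_en = x)
  fit <- nerni_vs_mean_en_fit(tab)
  expect_equal(fit$coefficients$estimate, c(0.05, 6, -80),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # pure noise explains (almost) nothing
  set.seed(10)
  r2 <- replicate(100, {
    tabn <- tibble::tibble(nerni = rnorm(200), mean_en = runif(200, 0, 0.3))
    nerni_vs_mean_en_fit(tabn)$r_squared
  })
  expect_lt(median(r2), 0.05)

  # noisy parabola: coefficients recovered within 2 standard errors
  set.seed(11)
  x <- runif(200, 0, 0.3)
  tab2 <- tibble::tibble(mean_en = x,
                         nerni = 0.003 + 8 * x - 89 * x^2 + rnorm(200, 0, 0.05))
  fit2 <- nerni_vs_mean_en_fit(tab2)
  expect_lt(abs(fit2$coefficients$estimate[2] - 8) /
              fit2$coefficients$std_error[2], 2.5)
  expect_lt(abs(fit2$coefficients$estimate[3] + 89) /
              fit2$coefficients$std_error[3], 2.5)
  expect_error(nerni_vs_mean_en_fit(tibble::tibble(nerni = 1:2,
                                                   mean_en = c(1, 1))),
               "distinct")
})
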