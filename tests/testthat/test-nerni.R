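test_that("hand-computed NERNI values are reproduced", {
  # effective single-node problem: w = 1, target = 1, K = 2, I = 1
  surf <- strip_surface(3)
  s <- subject_model("toy", surf,
                     leadfield(matrix(c(2, 0, 0), 3), "E1"),
                     target_map(c(1, 0, 0), c(1, 0, 0)))
  expect_equal(nerni(montage(c(E1 = 1)), s), 0, tolerance = 1e-15)
  # perfect fit at I = 0.5
  expect_equal(nerni(montage(c(E1 = 0.5)), s), 1, tolerance = 1e-15)
})

test_that("no intervention scores exactly zero", {
  for (seed in 1:3) {
    s <- random_subject(25, 4, seed = seed)
    expect_identical(nerni(montage(c(E1 = 0)), s), 0)
  }
})

test_that("any current reproducing the target scores one", {
  s <- random_subject(30, 5, seed = 2)
  set.seed(3)
  I0 <- runif(5, -1, 1)
  t <- as.numeric(s$leadfield$K %*% I0)
  s$target <- target_map(t, s$target$weights)
  m <- montage(setNames(I0, s$leadfield$electrode_labels))
  expect_equal(nerni(m, s), 1, tolerance = 1e-12)
  # doubling target and currents together preserves the perfect fit
  s2 <- s; s2$target <- target_map(2 * t, s$target$weights)
  m2 <- montage(setNames(2 * I0, s$leadfield$electrode_labels))
  expect_equal(nerni(m2, s2), 1, tolerance = 1e-12)
})

test_that("an all-zero weighted target raises an explicit error", {
  s <- random_subject(10, 2, seed = 4)
  s$target$en_trg <- rep(0, 10)
  expect_error(nerni(montage(c(E1 = 1)), s), "all-zero weighted target")
})

test_that("NERNI is concave in the currents", {
  set.seed(8)
  for (rep in 1:5) {
    s <- random_subject(15, 3, seed = rep + 10)
    I1 <- runif(3, -1, 1); I2 <- runif(3, -1, 1)
    f <- function(I) nerni(montage(setNames(I, s$leadfield$electrode_labels)), s)
    lam <- runif(1)
    expect_gte(f(lam * I1 + (1 - lam) * I2) + 1e-12,
               lam * f(I1) + (1 - lam) * f(I2))
  }
})

test_that("group NERNI is the arithmetic mean of subject NERNIs", {
  s1 <- random_subject(20, 3, seed = 1, id = "a")
  s2 <- random_subject(20, 3, seed = 2, id = "b")
  m <- montage(c(E1 = 0.5, E2 = -0.25, E3 = 0.4))
  a <- nerni(m, s1); b <- nerni(m, s2)
  expect_equal(nerni_group(m, list(s1)), a, tolerance = 1e-15)
  expect_equal(nerni_group(m, list(s1, s1)), a, tolerance = 1e-15)
  expect_equal(nerni_group(m, list(s1, s2)), (a + b) / 2, tolerance = 1e-12)
  set.seed(20)
  for (rep in 1:5) {
    subs <- lapply(1:4, function(i)
      random_subject(15, 3, seed = 100 * rep + i, id = paste0("s", i)))
    vals <- vapply(subs, function(s) nerni(m, s), 0)
    expect_equal(nerni_group(m, subs), mean(vals), tolerance = 1e-12)
  }
})

test_that("errors in group evaluation carry the subject id", {
  s1 <- random_subject(10, 2, seed = 1, id = "ok")
  s2 <- random_subject(10, 2, seed = 2, id = "broken")
  s2$target$en_trg <- rep(0, 10)
  expect_error(nerni_group(montage(c(E1 = 1)), list(s1, s2)), "broken")
})

test_that("mean En is the area-weighted target average and linear in I", {
  # two disjoint triangles with node areas 1 and 3 for the target nodes
  nodes <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0),
                 c(10, 0, 0), c(19, 0, 0), c(10, 2, 0))
  tris <- rbind(c(1, 2, 3), c(4, 5, 6))
  surf <- cortical_surface(nodes, tris, orient = FALSE)
  expect_equal(surf$node_areas[c(1, 4)], c(1, 3))
  K <- matrix(c(1, 0, 0, 3, 0, 0), 6)   # En = (1,0,0,3,0,0) per mA
  s <- subject_model("areas", surf, leadfield(K, "E1"),
                     target_map(c(0.25, 0, 0, 0.25, 0, 0),
                                c(10, 2, 2, 10, 2, 2)))
  expect_equal(mean_en(montage(c(E1 = 1)), s), (1 * 1 + 3 * 3) / 4,
               tolerance = 1e-12)
  expect_equal(mean_en(montage(c(E1 = 0.4)), s), 0.4 * 2.5,
               tolerance = 1e-12)
  expect_equal(mean_en(montage(c(E1 = 0)), s), 0)
  # uniform induced field over the target averages to itself
  K2 <- matrix(rep(0.7, 6), 6)
  s2 <- s; s2$leadfield <- leadfield(K2, "E1")
  expect_equal(mean_en(montage(c(E1 = 1)), s2), 0.7, tolerance = 1e-12)
  # empty target region errors
  s3 <- s; s3$target <- target_map(rep(0, 6), rep(1, 6))
  expect_error(mean_en(montage(c(E1 = 1)), s3), "empty target")
})

test_that("evaluate_montage bundles the fit metrics tidily", {
  s <- one_spherical_subject()
  m <- random_montage(s, seed = 2)
  fr <- evaluate_montage(m, s)
  expect_s3_class(fr, "fit_result")
  expect_equal(fr$nerni, nerni(m, s))
  td <- generics::tidy(fr)
  expect_named(td, c("subject_id", "nerni", "mean_en"))
})
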