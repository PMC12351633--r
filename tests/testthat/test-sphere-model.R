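# One reduced-resolution spherical subject shared by the tests below.
surf2 <- icosphere(2, 78)
spec2 <- spherical_head_spec()
lf2 <- spherical_leadfield(spec2, surf2)

test_that("lead-field columns superpose linearly", {
  K <- lf2$K
  en_sum <- K[, "F3"] + K[, "Pz"]
  I <- setNames(numeric(ncol(K)), colnames(K))
  I[c("F3", "Pz")] <- 1
  expect_equal(as.numeric(K %*% I), en_sum, tolerance = 1e-14)
})

test_that("swapping injection and return negates the field", {
  # column (F3 vs Cz) under reference Cz equals minus column (Cz vs F3)
  # under reference F3
  spec_f3 <- spherical_head_spec(reference_label = "F3")
  lf_f3 <- spherical_leadfield(spec_f3, surf2)
  expect_equal(lf_f3$K[, "Cz"], -lf2$K[, "F3"], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("closed-surface flux of En vanishes for any montage", {
  # flux quadrature error shrinks with mesh resolution: full tolerance at
  # subdivision 3, a proportionally looser one on the coarse mesh
  surf3 <- icosphere(3, 78)
  lf3 <- spherical_leadfield(spec2, surf3)
  set.seed(5)
  for (rep in 1:5) {
    labs <- sample(lf3$electrode_labels, 4)
    I <- setNames(numeric(ncol(lf3$K)), colnames(lf3$K))
    I[labs] <- runif(4, -1.5, 1.5)
    en3 <- as.numeric(lf3$K %*% I)
    expect_lt(abs(sum(en3 * surf3$node_areas)),
              1e-3 * sum(abs(en3) * surf3$node_areas))
    en2 <- as.numeric(lf2$K %*% I)
    expect_lt(abs(sum(en2 * surf2$node_areas)),
              5e-3 * sum(abs(en2) * surf2$node_areas))
  }
})

test_that("the forward model is rotationally equivariant", {
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  spec_rot <- spherical_head_spec(
    electrode_positions = lapply(spec2$electrode_positions,
                                 function(p) as.numeric(R %*% p)))
  surf_rot <- cortical_surface(t(R %*% t(surf2$nodes)), surf2$triangles)
  lf_rot <- spherical_leadfield(spec_rot, surf_rot)
  expect_lt(max(abs(lf_rot$K - lf2$K)) / max(abs(lf2$K)), 1e-6)
})

test_that("En decays from the injection site to the antipode", {
  u <- surf2$nodes / 78
  for (lab in c("F3", "Oz", "T8")) {
    co <- as.numeric(u %*% spec2$electrode_positions[[lab]])
    near <- abs(lf2$K[which.max(co), lab])
    far <- abs(lf2$K[which.min(co), lab])
    expect_gt(near, far)
  }
})

test_that("positive En points into the cortex under the anode", {
  u <- surf2$nodes / 78
  co <- as.numeric(u %*% spec2$electrode_positions[["F3"]])
  expect_gt(lf2$K[which.max(co), "F3"], 0)
})

test_that("an under-resolved series errors with advice", {
  spec_low <- spherical_head_spec(series_order = 30L)
  expect_error(spherical_leadfield(spec_low, surf2), "series_order")
})

test_that("non-unit electrode directions are rejected", {
  pos <- electrode_positions_1010()
  pos$F3 <- pos$F3 * 1.1
  expect_error(spherical_head_spec(electrode_positions = pos), "unit")
})

test_that("the homogeneous sphere matches its closed-form series", {
  g <- tesgroup:::sphere_series_coeffs(92, 0.33, 78, 120)
  n <- seq_len(120)
  closed <- 1e-3 * (2 * n + 1) / (4 * pi * 0.33 * 0.092) *
    (78 / 92)^(n - 1) / 0.092
  expect_equal(g, closed, tolerance = 1e-12)
})

test_that("the 10-10 electrode set has 39 unit-vector positions", {
  pos <- electrode_positions_1010()
  expect_length(pos, 39)
  expect_true("Cz" %in% names(pos))
  expect_equal(vapply(pos, function(p) sum(p^2), 0),
               setNames(rep(1, 39), names(pos)), tolerance = 1e-12)
  # left/right symmetry of homologous pairs
  f3 <- pos$F3; f4 <- pos$F4
  expect_equal(f3 * c(-1, 1, 1), f4, tolerance = 1e-12)
})
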