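test_that("coplanar surfaces have the plane normal at every node", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  tris <- rbind(c(1, 2, 3), c(1, 3, 4))
  s <- cortical_surface(nodes, tris)
  expect_equal(abs(s$node_normals[, 3]), rep(1, 4), tolerance = 1e-12)
  expect_equal(s$node_normals[, 1:2], matrix(0, 4, 2), tolerance = 1e-12)
})

test_that("node normals follow the area-weighted rule on a two-triangle fan", {
  # shared edge 1-2; triangle areas 1 and 3 with different normals; the
  # node normal must equal normalize(area1 * n1 + area2 * n2)
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0, 0, -6))
  tris <- rbind(c(1, 2, 3), c(2, 1, 4))
  s <- cortical_surface(nodes, tris, orient = FALSE)
  tri_normal <- function(a, b, cc) {
    v <- vec_cross(nodes[b, ] - nodes[a, ], nodes[cc, ] - nodes[a, ])
    list(n = v / sqrt(sum(v^2)), area = sqrt(sum(v^2)) / 2)
  }
  t1 <- tri_normal(1, 2, 3); t2 <- tri_normal(2, 1, 4)
  expect_equal(t1$area, 1); expect_equal(t2$area, 3)
  expected <- t1$area * t1$n + t2$area * t2$n
  expected <- expected / sqrt(sum(expected^2))
  expect_equal(abs(sum(s$node_normals[1, ] * expected)), 1,
               tolerance = 1e-12)
})

test_that("icosphere node normals converge to the radial direction", {
  errs <- vapply(2:4, function(sub) {
    s <- icosphere(sub, 80)
    u <- s$nodes / sqrt(rowSums(s$nodes^2))
    max(acos(pmin(1, rowSums(u * s$node_normals))))
  }, numeric(1))
  # the area-weighted rule is first-order on irregular fans: error halves
  # per subdivision level from ~2.4e-2 at level 2
  expect_lt(errs[1], 0.025)
  expect_lt(errs[2], 0.013)
  expect_lt(errs[3], 0.007)
  expect_true(all(diff(errs) < 0))
})

test_that("node areas partition the surface area", {
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  s <- cortical_surface(nodes, rbind(c(1, 2, 3)))
  expect_equal(s$node_areas, rep(2 / 3, 3), tolerance = 1e-12)

  sp <- icosphere(3, 80)
  tri_total <- sum(tesgroup:::triangle_areas(sp$nodes, sp$triangles))
  expect_equal(sum(sp$node_areas), tri_total, tolerance = 1e-12)
  # approaches the analytic sphere area from below as resolution grows
  a2 <- sum(icosphere(2, 80)$node_areas)
  expect_equal(sum(sp$node_areas) / (4 * pi * 80^2), 1, tolerance = 6e-3)
  expect_gt(sum(sp$node_areas), a2)
})

test_that("reversing every triangle flips every node normal", {
  s <- icosphere(1, 10)
  rev <- s$triangles[, c(1, 3, 2)]
  s2 <- list(nodes = s$nodes, triangles = rev)
  n2 <- compute_node_normals(s2)
  expect_equal(n2, -s$node_normals, tolerance = 1e-12)
})

test_that("construction rejects invalid surfaces", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(cortical_surface(nodes, rbind(c(1, 2, 3))), "degenerate")
  expect_error(cortical_surface(nodes[1:2, ], rbind(c(1, 2, 2))), "repeated")
  expect_error(cortical_surface(nodes, rbind(c(1, 2, 4))), "out of range")
  # node 4 not in any triangle
  nodes4 <- rbind(nodes, c(0, 5, 0), c(0, 0, 7))
  nodes4[3, ] <- c(0, 1, 0)
  expect_error(
    compute_node_normals(list(nodes = nodes4,
                              triangles = rbind(c(1, 2, 3)))),
    "not contained in any triangle")
})

test_that("triangle orientation is made globally consistent", {
  s <- icosphere(1, 5)
  # scramble windings, rebuild; normals must all point outward again
  tris <- s$triangles
  flip <- seq(1, nrow(tris), by = 3)
  tris[flip, ] <- tris[flip, c(1, 3, 2)]
  s2 <- cortical_surface(s$nodes, tris, orient = TRUE)
  u <- s2$nodes / sqrt(rowSums(s2$nodes^2))
  expect_true(all(rowSums(u * s2$node_normals) > 0.9))
})
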