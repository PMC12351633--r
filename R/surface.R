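#' Triangulated cortical (or scalp) surface
#'
#' A `cortical_surface` is a light container for a triangulated surface:
#' node positions in millimetres, triangle connectivity, and the derived
#' per-node outward unit normals and per-node areas used throughout the
#' package. Normals follow the area-weighted average of incident triangle
#' normals; the per-node area is one third of the summed area of the
#' triangles sharing the node, so that node areas partition the total
#' surface area.
#'
#' The sign convention for the normal component of the electric field (En)
#' is tied to these normals: normals point outward from the surface, and a
#' positive En means the field points *into* the surface (toward the
#' cortex), the direction that depolarizes pyramidal somas.
#'
#' @param nodes numeric matrix, n x 3, node positions (mm).
#' @param triangles integer matrix, m x 3, 1-based node indices per triangle.
#' @param orient logical; if `TRUE` (default) triangle windings are made
#'   globally consistent by breadth-first propagation across shared edges and
#'   flipped, if needed, so normals point away from the surface centroid.
#' @return An object of class `cortical_surface` with elements `nodes`,
#'   `triangles`, `node_normals`, `node_areas`.
#' @examples
#' s <- icosphere(2, radius = 80)
#' sum(s$node_areas) / (4 * pi * 80^2)
#' @export
cortical_surface <- function(nodes, triangles, orient = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(nodes) != 3L) stop("`nodes` must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("`triangles` must be an m x 3 matrix")
  if (nrow(triangles) < 1L) stop("surface must have at least one triangle")
  n <- nrow(nodes)
  if (any(triangles < 1L) || any(triangles > n))
    stop("triangle indices out of range [1, ", n, "]")
  if (any(triangles[, 1] == triangles[, 2] | triangles[, 1] == triangles[, 3] |
            triangles[, 2] == triangles[, 3]))
    stop("triangles with repeated node indices are not allowed")

  areas <- triangle_areas(nodes, triangles)
  if (any(areas < 1e-12))
    stop("degenerate (zero-area) triangle(s) at row(s): ",
         paste(utils::head(which(areas < 1e-12), 5L), collapse = ", "))

  if (orient) triangles <- orient_triangles(nodes, triangles)

  surf <- structure(
    list(nodes = nodes, triangles = triangles,
         node_normals = NULL, node_areas = NULL),
    class = "cortical_surface")
  surf$node_normals <- compute_node_normals(surf)
  surf$node_areas <- compute_node_areas(surf)
  surf
}

#' @export
print.cortical_surface <- function(x, ...) {
  cat("<cortical_surface> ", nrow(x$nodes), " nodes, ",
      nrow(x$triangles), " triangles, total area ",
      format(sum(x$node_areas), digits = 6), " mm^2\n", sep = "")
  invisible(x)
}

# Per-triangle (unnormalized) normal vectors, m x 3; right-hand rule.
triangle_normals_raw <- function(nodes, triangles) {
  p1 <- nodes[triangles[, 1], , drop = FALSE]
  e1 <- nodes[triangles[, 2], , drop = FALSE] - p1
  e2 <- nodes[triangles[, 3], , drop = FALSE] - p1
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
}

triangle_areas <- function(nodes, triangles) {
  cr <- triangle_normals_raw(nodes, triangles)
  sqrt(rowSums(cr^2))
}

# Make triangle windings globally consistent by BFS over shared edges, then
# flip all if the mean (normal . outward-from-centroid) is negative.
orient_triangles <- function(nodes, triangles) {
  m <- nrow(triangles)
  if (m == 1L) return(fix_outward(nodes, triangles))
  # edge -> triangle incidence
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(
    cbind(triangles[, 1], triangles[, 2]),
    cbind(triangles[, 2], triangles[, 3]),
    cbind(triangles[, 3], triangles[, 1]))
  keys <- ek(edges[, 1], edges[, 2])
  tri_of_edge <- rep.int(seq_len(m), 3L)
  inc <- split(tri_of_edge, keys)
  if (any(lengths(inc) > 2L)) stop("non-manifold edge: surface not orientable")

  flipped <- logical(m)
  visited <- logical(m)
  # directed edges per triangle in current winding
  directed <- function(t) {
    tri <- triangles[t, ]
    if (flipped[t]) tri <- tri[c(1L, 3L, 2L)]
    rbind(tri[c(1L, 2L)], tri[c(2L, 3L)], tri[c(3L, 1L)])
  }
  for (seed in seq_len(m)) {
    if (visited[seed]) next
    queue <- seed
    visited[seed] <- TRUE
    while (length(queue)) {
      t <- queue[[1L]]; queue <- queue[-1L]
      de <- directed(t)
      for (r in 1:3) {
        a <- de[r, 1L]; b <- de[r, 2L]
        nb <- inc[[ek(a, b)]]
        nb <- nb[nb != t]
        if (!length(nb)) next
        u <- nb[[1L]]
        du <- directed(u)
        # consistent orientation: neighbour traverses the shared edge b->a
        same_dir <- any(du[, 1L] == a & du[, 2L] == b)
        if (!visited[u]) {
          if (same_dir) flipped[u] <- !flipped[u]
          visited[u] <- TRUE
          queue <- c(queue, u)
        } else {
          now_same <- any(directed(u)[, 1L] == a & directed(u)[, 2L] == b)
          if (now_same) stop("surface is non-orientable")
        }
      }
    }
  }
  if (any(flipped))
    triangles[flipped, ] <- triangles[flipped, c(1L, 3L, 2L), drop = FALSE]
  fix_outward(nodes, triangles)
}

fix_outward <- function(nodes, triangles) {
  nr <- triangle_normals_raw(nodes, triangles)
  ctr <- colMeans(nodes)
  cent <- (nodes[triangles[, 1], , drop = FALSE] +
             nodes[triangles[, 2], , drop = FALSE] +
             nodes[triangles[, 3], , drop = FALSE]) / 3
  out <- sweep(cent, 2, ctr)
  if (sum(rowSums(nr * out)) < 0)
    triangles <- triangles[, c(1L, 3L, 2L), drop = FALSE]
  triangles
}

#' Area-weighted per-node unit normals
#'
#' Each node normal is the normalized area-weighted average of the normals
#' of the triangles containing the node (weights are the triangle areas;
#' since a raw triangle cross product already has magnitude proportional to
#' its area, the weighting is the plain sum of raw cross products).
#'
#' @param surface a `cortical_surface` (or a bare list with `nodes`,
#'   `triangles`).
#' @return n x 3 matrix of unit vectors.
#' @export
compute_node_normals <- function(surface) {
  nodes <- surface$nodes; triangles <- surface$triangles
  nr <- triangle_normals_raw(nodes, triangles)   # magnitude = area
  n <- nrow(nodes)
  acc <- matrix(0, n, 3)
  idx <- as.vector(triangles)
  for (j in 1:3) {
    v <- rowsum(rep(nr[, j], 3L), group = idx, reorder = FALSE)
    acc[as.integer(rownames(v)), j] <- v
  }
  deg <- tabulate(idx, nbins = n)
  if (any(deg == 0L))
    stop("node(s) not contained in any triangle: ",
         paste(utils::head(which(deg == 0L), 5L), collapse = ", "))
  len <- sqrt(rowSums(acc^2))
  if (any(len < 1e-14))
    stop("zero resultant normal at node(s): ",
         paste(utils::head(which(len < 1e-14), 5L), collapse = ", "))
  acc / len
}

#' Per-node areas
#'
#' The node area is the sum of the areas of all triangles sharing the node,
#' divided by 3, so that node areas sum exactly to the total triangle area.
#'
#' @inheritParams compute_node_normals
#' @return numeric vector of areas (mm^2).
#' @export
compute_node_areas <- function(surface) {
  nodes <- surface$nodes; triangles <- surface$triangles
  a <- triangle_areas(nodes, triangles)
  n <- nrow(nodes)
  acc <- numeric(n)
  idx <- as.vector(triangles)
  v <- rowsum(rep(a, 3L), group = idx, reorder = FALSE)
  acc[as.integer(rownames(v))] <- v
  acc / 3
}

#' Icosphere surface
#'
#' Triangulated sphere obtained by repeated 4-way subdivision of an
#' icosahedron with reprojection to the sphere. Used as the synthetic
#' cortical and scalp surface.
#'
#' @param subdivisions non-negative integer; 0 is the raw icosahedron
#'   (12 nodes), each level quadruples the triangle count.
#' @param radius sphere radius (mm).
#' @return a `cortical_surface`.
#' @export
icosphere <- function(subdivisions = 3L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midpoint_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- p
      midpoint_cache[[key]] <- nv
      nv
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- mid(a, b); bc <- mid(b, cc); ca <- mid(cc, a)
      nf[(t - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, c(list(v), vlist[-1]))
    f <- nf
  }
  cortical_surface(v * radius, f, orient = TRUE)
}
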