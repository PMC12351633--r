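#' Tetrahedral head mesh
#'
#' Container for a labelled tetrahedral mesh: node positions (mm),
#' tetrahedron connectivity, and a tissue label per tetrahedron drawn from
#' the head-tissue enumeration `scalp`, `skull`, `csf`, `gm`, `wm`.
#' Tetrahedra are re-ordered on construction so that every signed volume is
#' positive.
#'
#' @param nodes numeric matrix, n x 3 (mm).
#' @param tetrahedra integer matrix, m x 4, 1-based node indices.
#' @param tissue_label character or factor of length m.
#' @return object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tetrahedra, tissue_label) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tetrahedra <- as.matrix(tetrahedra); storage.mode(tetrahedra) <- "integer"
  if (ncol(nodes) != 3L) stop("`nodes` must be n x 3")
  if (ncol(tetrahedra) != 4L) stop("`tetrahedra` must be m x 4")
  tissue_label <- as.character(tissue_label)
  if (length(tissue_label) != nrow(tetrahedra))
    stop("one tissue label per tetrahedron required")
  bad <- setdiff(unique(tissue_label), tes_tissues())
  if (length(bad))
    stop("unknown tissue label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(tes_tissues(), collapse = ", "), ")")
  if (any(tetrahedra < 1L) || any(tetrahedra > nrow(nodes)))
    stop("tetrahedron indices out of range")
  sv <- tet_signed_volumes(nodes, tetrahedra)
  if (any(abs(sv) < 1e-12))
    stop("degenerate tetrahedron (zero volume) at row(s): ",
         paste(utils::head(which(abs(sv) < 1e-12), 5L), collapse = ", "))
  neg <- sv < 0
  if (any(neg))
    tetrahedra[neg, ] <- tetrahedra[neg, c(1L, 2L, 4L, 3L), drop = FALSE]
  structure(list(nodes = nodes, tetrahedra = tetrahedra,
                 tissue_label = tissue_label),
            class = "tet_mesh")
}

#' Head tissue enumeration
#' @return character vector of valid tissue labels.
#' @export
tes_tissues <- function() c("scalp", "skull", "csf", "gm", "wm")

#' @export
print.tet_mesh <- function(x, ...) {
  cat("<tet_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$tetrahedra),
      " tetrahedra (", paste(unique(x$tissue_label), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

tet_signed_volumes <- function(nodes, tetrahedra) {
  p1 <- nodes[tetrahedra[, 1], , drop = FALSE]
  a <- nodes[tetrahedra[, 2], , drop = FALSE] - p1
  b <- nodes[tetrahedra[, 3], , drop = FALSE] - p1
  d <- nodes[tetrahedra[, 4], , drop = FALSE] - p1
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
     a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
     a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' Tissue volumes of a tetrahedral mesh
#'
#' Sums the (absolute) volume of every tetrahedron per tissue label.
#'
#' @param mesh a `tet_mesh`.
#' @return tibble with columns `tissue`, `volume_mm3`, one row per tissue
#'   present in the mesh, ordered by the tissue enumeration.
#' @export
tissue_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  v <- abs(tet_signed_volumes(mesh$nodes, mesh$tetrahedra))
  agg <- tapply(v, factor(mesh$tissue_label, levels = tes_tissues()), sum)
  agg <- agg[!is.na(agg)]
  tibble::tibble(tissue = names(agg), volume_mm3 = as.numeric(agg))
}

#' Synthetic concentric-shell tetrahedral mesh
#'
#' Builds a labelled tet mesh of nested spherical shells (plus a solid core
#' for the innermost tissue) by extruding an icosphere triangulation between
#' consecutive radii: each triangular prism is split into three tetrahedra,
#' and the core is tetrahedralized by coning the innermost surface to the
#' centre. Used by the synthetic cohort so that tissue-volume anatomical
#' features come from actual mesh integration.
#'
#' @param radii strictly increasing numeric vector of interface radii (mm);
#'   `radii[1]` bounds the solid core.
#' @param tissues character vector, `length(radii)` labels: core tissue
#'   first, then one label per shell.
#' @param subdivisions icosphere subdivision level (default 2).
#' @return a `tet_mesh`.
#' @export
shell_tet_mesh <- function(radii, tissues, subdivisions = 2L) {
  stopifnot(length(radii) == length(tissues), all(diff(radii) > 0))
  base <- icosphere(subdivisions, radius = 1)
  nv <- nrow(base$nodes)
  tri <- base$triangles
  layers <- lapply(radii, function(r) base$nodes * r)
  nodes <- rbind(c(0, 0, 0), do.call(rbind, layers))
  off <- function(k) 1L + (k - 1L) * nv   # node offset of layer k

  tets <- list(); labs <- list()
  # solid core: cone each innermost triangle to the centre node (index 1)
  core <- cbind(1L, tri + off(1L))
  tets[[1]] <- core; labs[[1]] <- rep(tissues[1], nrow(core))
  # shells: prism between layer k and k+1 split into 3 tets
  for (k in seq_len(length(radii) - 1L)) {
    a <- tri + off(k); b <- tri + off(k + 1L)
    # split prism (a1 a2 a3 | b1 b2 b3) consistently using vertex ordering
    t1 <- cbind(a[, 1], a[, 2], a[, 3], b[, 1])
    t2 <- cbind(a[, 2], a[, 3], b[, 1], b[, 2])
    t3 <- cbind(a[, 3], b[, 1], b[, 2], b[, 3])
    tets[[k + 1L]] <- rbind(t1, t2, t3)
    labs[[k + 1L]] <- rep(tissues[k + 1L], 3L * nrow(tri))
  }
  tet_mesh(nodes, do.call(rbind, tets), unlist(labs))
}
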