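#' Read a Gmsh MSH (ASCII v2.2) file
#'
#' Parses `$Nodes` and `$Elements` sections; triangles (element type 2)
#' become a `cortical_surface`, tetrahedra (type 4) a `tet_mesh`. The first
#' element tag (physical group) carries the tissue label for tetrahedra via
#' `tissue_map`.
#'
#' @param path file path.
#' @param tissue_map named integer vector mapping tissue label -> physical
#'   tag, e.g. `c(scalp = 5, skull = 4, csf = 3, gm = 2, wm = 1)`.
#'   Required when the file contains tetrahedra.
#' @return a list with components `surface` (`cortical_surface` or `NULL`)
#'   and `mesh` (`tet_mesh` or `NULL`).
#' @export
read_msh <- function(path, tissue_map = NULL) {
  lines <- readLines(path)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) return(NULL)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- sect("MeshFormat")
  if (is.null(fmt)) stop("not a Gmsh MSH file: ", path)
  ver <- strsplit(trimws(fmt[1]), "\\s+")[[1]][1]
  if (!startsWith(ver, "2.2"))
    stop("only MSH ASCII v2.2 is supported (got version ", ver, ")")

  nl <- sect("Nodes")
  n <- as.integer(nl[1])
  ntab <- matrix(as.numeric(unlist(strsplit(trimws(nl[1 + seq_len(n)]), "\\s+"))),
                 ncol = 4, byrow = TRUE)
  if (!all(ntab[, 1] == seq_len(n)))
    stop("non-contiguous node numbering is not supported")
  nodes <- ntab[, 2:4, drop = FALSE]

  el <- sect("Elements")
  m <- as.integer(el[1])
  tris <- list(); tets <- list(); tet_tags <- list()
  for (ln in el[1 + seq_len(m)]) {
    f <- as.integer(strsplit(trimws(ln), "\\s+")[[1]])
    type <- f[2]; ntags <- f[3]
    tags <- if (ntags > 0) f[3 + seq_len(ntags)] else integer(0)
    conn <- f[(4 + ntags):length(f)]
    if (type == 2L) {
      tris[[length(tris) + 1L]] <- conn
    } else if (type == 4L) {
      tets[[length(tets) + 1L]] <- conn
      tet_tags[[length(tet_tags) + 1L]] <- if (length(tags)) tags[1] else NA_integer_
    } # other element types (points, lines) are skipped
  }
  surface <- NULL; mesh <- NULL
  if (length(tris))
    surface <- cortical_surface(nodes, do.call(rbind, tris))
  if (length(tets)) {
    tags <- unlist(tet_tags)
    if (is.null(tissue_map))
      stop("file contains tetrahedra: supply `tissue_map` (label -> physical tag)")
    lab <- names(tissue_map)[match(tags, tissue_map)]
    if (anyNA(lab))
      stop("physical tag(s) with no tissue mapping: ",
           paste(unique(tags[is.na(lab)]), collapse = ", "))
    mesh <- tet_mesh(nodes, do.call(rbind, tets), lab)
  }
  list(surface = surface, mesh = mesh)
}

#' Write a Gmsh MSH (ASCII v2.2) file
#'
#' Writes a `cortical_surface` (element type 2) and/or a `tet_mesh`
#' (element type 4, physical tag = tissue index per `tissue_map`) sharing
#' one node block. When both are given they must use the same node array.
#'
#' @param path output path.
#' @param surface optional `cortical_surface`.
#' @param mesh optional `tet_mesh`.
#' @param tissue_map named integer vector mapping tissue label -> physical
#'   tag; defaults to the enumeration order of [tes_tissues()].
#' @return `path`, invisibly.
#' @export
write_msh <- function(path, surface = NULL, mesh = NULL,
                      tissue_map = stats::setNames(seq_along(tes_tissues()),
                                                   tes_tissues())) {
  if (is.null(surface) && is.null(mesh))
    stop("nothing to write: supply `surface` and/or `mesh`")
  nodes <- if (!is.null(mesh)) mesh$nodes else surface$nodes
  if (!is.null(surface) && !is.null(mesh) &&
        !isTRUE(all.equal(surface$nodes, mesh$nodes)))
    stop("surface and mesh must share one node array")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
  w("$Nodes", as.character(nrow(nodes)))
  w(paste(seq_len(nrow(nodes)),
          format(nodes[, 1], digits = 17, trim = TRUE, scientific = FALSE),
          format(nodes[, 2], digits = 17, trim = TRUE, scientific = FALSE),
          format(nodes[, 3], digits = 17, trim = TRUE, scientific = FALSE)))
  w("$EndNodes")
  elems <- character(0)
  id <- 0L
  if (!is.null(surface)) {
    tr <- surface$triangles
    ids <- id + seq_len(nrow(tr)); id <- id + nrow(tr)
    elems <- c(elems, paste(ids, 2, 2, 0, 0, tr[, 1], tr[, 2], tr[, 3]))
  }
  if (!is.null(mesh)) {
    tt <- mesh$tetrahedra
    ptag <- tissue_map[mesh$tissue_label]
    ids <- id + seq_len(nrow(tt)); id <- id + nrow(tt)
    elems <- c(elems, paste(ids, 4, 2, ptag, ptag,
                            tt[, 1], tt[, 2], tt[, 3], tt[, 4]))
  }
  w("$Elements", as.character(length(elems)), elems, "$EndElements")
  invisible(path)
}
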