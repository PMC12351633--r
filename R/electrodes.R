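#' Idealized 10-10 electrode directions on a spherical scalp
#'
#' Unit direction vectors for a 39-position subset of the 10-10 EEG system
#' on an idealized spherical head. Coordinates are right-handed with +x to
#' the subject's right, +y anterior, +z through the vertex (Cz). Midline and
#' temporal-ring positions follow the standard 10-10 arc construction
#' (sagittal arc nasion->inion in 10% steps; the 10% ring through Fpz, T7,
#' Oz, T8); intermediate positions are spherical interpolations between
#' their midline and ring anchors, the usual idealization when no
#' subject-specific digitization exists.
#'
#' @param labels optional character vector to subset/order the returned set.
#' @return named list of unit 3-vectors (one per label).
#' @export
electrode_positions_1010 <- function(labels = NULL) {
  deg <- pi / 180
  # direction from inclination (angle from vertex) and azimuth
  # (0 = anterior midline, positive toward the left hemisphere)
  dir <- function(incl, azim) {
    c(-sin(incl) * sin(azim), sin(incl) * cos(azim), cos(incl))
  }
  slerp <- function(a, b, t) {
    w <- acos(max(-1, min(1, sum(a * b))))
    if (w < 1e-12) return(a)
    v <- (sin((1 - t) * w) * a + sin(t * w) * b) / sin(w)
    v / sqrt(sum(v^2))
  }
  pos <- list()
  # sagittal midline, 18-degree (10%) steps from the vertex
  mid <- c(Fpz = 72, AFz = 54, Fz = 36, FCz = 18, Cz = 0)
  for (l in names(mid)) pos[[l]] <- dir(mid[[l]] * deg, 0)
  midb <- c(CPz = 18, Pz = 36, POz = 54, Oz = 72)
  for (l in names(midb)) pos[[l]] <- dir(midb[[l]] * deg, pi)
  # 10% ring (inclination 72 deg), azimuth in 36-degree steps from Fpz;
  # left-hemisphere azimuths positive, right mirrored
  ring <- c(Fp1 = 18, F7 = 54, T7 = 90, P7 = 126, O1 = 162)
  for (l in names(ring)) pos[[l]] <- dir(72 * deg, ring[[l]] * deg)
  ringr <- c(Fp2 = 18, F8 = 54, T8 = 90, P8 = 126, O2 = 162)
  for (l in names(ringr)) pos[[l]] <- dir(72 * deg, -ringr[[l]] * deg)
  # coronal arc through the vertex
  cor <- c(C1 = 18, C3 = 36, C5 = 54)
  for (l in names(cor)) pos[[l]] <- dir(cor[[l]] * deg, pi / 2)
  corr <- c(C2 = 18, C4 = 36, C6 = 54)
  for (l in names(corr)) pos[[l]] <- dir(corr[[l]] * deg, -pi / 2)
  # intermediate rows: slerp between midline and ring anchors
  ft7 <- dir(72 * deg, 72 * deg); ft8 <- dir(72 * deg, -72 * deg)
  tp7 <- dir(72 * deg, 108 * deg); tp8 <- dir(72 * deg, -108 * deg)
  pos$F3 <- slerp(pos$Fz, pos$F7, 0.5);  pos$F4 <- slerp(pos$Fz, pos$F8, 0.5)
  pos$F5 <- slerp(pos$Fz, pos$F7, 0.75); pos$F6 <- slerp(pos$Fz, pos$F8, 0.75)
  pos$FC3 <- slerp(pos$FCz, ft7, 0.5);   pos$FC4 <- slerp(pos$FCz, ft8, 0.5)
  pos$CP3 <- slerp(pos$CPz, tp7, 0.5);   pos$CP4 <- slerp(pos$CPz, tp8, 0.5)
  pos$P3 <- slerp(pos$Pz, pos$P7, 0.5);  pos$P4 <- slerp(pos$Pz, pos$P8, 0.5)
  pos$P5 <- slerp(pos$Pz, pos$P7, 0.75); pos$P6 <- slerp(pos$Pz, pos$P8, 0.75)
  pos$AF3 <- slerp(pos$AFz, pos$Fp1, 0.5)
  pos$AF4 <- slerp(pos$AFz, pos$Fp2, 0.5)
  if (!is.null(labels)) {
    missing <- setdiff(labels, names(pos))
    if (length(missing))
      stop("unknown electrode label(s): ", paste(missing, collapse = ", "))
    pos <- pos[labels]
  }
  pos
}

#' Scalp landmark directions on the idealized sphere
#'
#' Nasion (Nz) and inion (Iz) on the anterior/posterior mid-sagittal
#' equator, pre-auricular points (LPA/RPA) on the lateral coronal equator,
#' and Cz at the vertex.
#'
#' @return named list of unit 3-vectors.
#' @export
landmark_directions <- function() {
  list(Nz = c(0, 1, 0), Iz = c(0, -1, 0),
       LPA = c(-1, 0, 0), RPA = c(1, 0, 0), Cz = c(0, 0, 1))
}
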