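#' Multi-shell spherical head model specification
#'
#' Concentric-sphere volume conductor with point electrodes on the scalp
#' sphere and an analytic (Legendre-series) forward solution. The default
#' four shells are brain, CSF, skull and scalp with outer radii
#' 78/80/86/92 mm and isotropic conductivities 0.40, 1.79, 0.008 and
#' 0.33 S/m (standard head-modelling values; the brain shell carries the
#' gray-matter conductivity since gray and white matter are merged for the
#' forward solve). The cortical evaluation sphere sits at the brain shell's
#' outer radius.
#'
#' @param shell_radii strictly increasing named numeric, outer radius (mm)
#'   per shell, innermost first.
#' @param shell_conductivities positive numeric, S/m per shell, same order.
#' @param electrode_positions named list of unit 3-vectors (scalp
#'   directions); default the built-in 39-label 10-10 subset.
#' @param cortical_radius evaluation sphere radius (mm), at most the
#'   innermost shell radius; default that radius.
#' @param series_order maximum Legendre degree of the truncated series.
#' @param reference_label fixed reference (cathode) label, default `"Cz"`.
#' @return object of class `spherical_head_spec`.
#' @export
spherical_head_spec <- function(
    shell_radii = c(brain = 78, csf = 80, skull = 86, scalp = 92),
    shell_conductivities = c(brain = 0.40, csf = 1.79,
                             skull = 0.008, scalp = 0.33),
    electrode_positions = electrode_positions_1010(),
    cortical_radius = NULL,
    series_order = 200L,
    reference_label = "Cz") {
  if (any(diff(shell_radii) <= 0)) stop("shell radii must be strictly increasing")
  if (any(shell_conductivities <= 0)) stop("conductivities must be positive")
  if (length(shell_radii) != length(shell_conductivities))
    stop("one conductivity per shell required")
  if (is.null(cortical_radius)) cortical_radius <- shell_radii[[1]]
  if (cortical_radius > shell_radii[[1]] + 1e-9)
    stop("cortical_radius must not exceed the innermost shell radius")
  if (series_order < 1) stop("series_order must be >= 1")
  lens <- vapply(electrode_positions, function(p) sqrt(sum(p^2)), 0)
  if (any(abs(lens - 1) > 1e-6))
    stop("electrode direction(s) not unit vectors: ",
         paste(names(electrode_positions)[abs(lens - 1) > 1e-6], collapse = ", "))
  if (!reference_label %in% names(electrode_positions))
    stop("reference label ", reference_label, " not among electrode positions")
  structure(list(shell_radii = shell_radii,
                 shell_conductivities = shell_conductivities,
                 electrode_positions = electrode_positions,
                 cortical_radius = cortical_radius,
                 series_order = as.integer(series_order),
                 reference_label = reference_label),
            class = "spherical_head_spec")
}

#' @export
print.spherical_head_spec <- function(x, ...) {
  cat("<spherical_head_spec> shells (mm): ",
      paste(sprintf("%s=%g", names(x$shell_radii), x$shell_radii),
            collapse = ", "),
      "; ", length(x$electrode_positions), " electrodes, reference ",
      x$reference_label, "\n", sep = "")
  invisible(x)
}

# Radial-derivative series coefficients for a 1 mA point injection on the
# scalp sphere of an N-layer concentric conductor: returns g[n], n = 1..L,
# such that dV/dr at radius r_eval and angular distance theta from the
# electrode equals sum_n g[n] P_n(cos theta), in V/m per mA. The n = 0 term
# vanishes for balanced electrode pairs and is omitted.
sphere_series_coeffs <- function(radii_mm, sigmas, r_eval_mm, order) {
  nlay <- length(radii_mm)
  RN <- radii_mm[nlay] * 1e-3            # scalp radius in metres
  rho <- radii_mm / radii_mm[nlay]       # scaled interface radii
  rho_c <- r_eval_mm / radii_mm[nlay]
  I0 <- 1e-3                             # 1 mA in amperes
  g <- numeric(order)
  for (n in seq_len(order)) {
    A <- 1; B <- 0                       # regular solution in the core
    for (j in seq_len(nlay - 1L)) {
      rj <- rho[j]
      V <- A * rj^n + B * rj^(-(n + 1))
      Fl <- sigmas[j] * (n * A * rj^(n - 1) - (n + 1) * B * rj^(-(n + 2)))
      # closed-form continuity solve (well-scaled for large n)
      Fs <- Fl / sigmas[j + 1]
      Anew <- ((n + 1) * V * rj^(-n) + Fs * rj^(1 - n)) / (2 * n + 1)
      Bnew <- (n * V * rj^(n + 1) - Fs * rj^(n + 2)) / (2 * n + 1)
      A <- Anew; B <- Bnew
    }
    denom <- n * A - (n + 1) * B         # at rho = 1
    scale <- I0 * (2 * n + 1) / (4 * pi * sigmas[nlay] * RN) / denom
    # coefficient of P_n in dV/dr within the core, evaluated at rho_c
    g[n] <- scale * n * rho_c^(n - 1) / RN
  }
  g
}

# Estimate the relative series tail and stop if it exceeds `tol`.
check_series_convergence <- function(g, tol = 1e-8) {
  L <- length(g)
  if (L < 20) stop("series_order too small for a convergence estimate")
  tail_mag <- abs(g[L])
  q <- (abs(g[L]) / abs(g[L - 10L]))^(1 / 10)
  if (!is.finite(q) || q >= 1)
    stop("Legendre series not converging at order ", L,
         "; increase `series_order`")
  tail_est <- tail_mag * q / (1 - q)
  total <- sum(abs(g))
  if (tail_est > tol * total)
    stop(sprintf(paste0(
      "Legendre series truncation error ~%.2e (relative %.2e) exceeds ",
      "tolerance %g at order %d; increase `series_order`"),
      tail_est, tail_est / total, tol, L))
  invisible(tail_est / total)
}

# Evaluate sum_n g[n] P_n(x) for a vector x via the Legendre recurrence.
legendre_series <- function(g, x) {
  Pm1 <- rep(1, length(x))   # P_0
  P <- x                     # P_1
  s <- g[1] * P
  L <- length(g)
  if (L >= 2) for (n in 1:(L - 1)) {
    Pn1 <- ((2 * n + 1) * x * P - n * Pm1) / (n + 1)
    s <- s + g[n + 1] * Pn1
    Pm1 <- P; P <- Pn1
  }
  s
}

#' Analytic lead-field of the spherical head model
#'
#' For every non-reference electrode, computes the normal field component
#' En on the cortical surface nodes for a +1 mA point injection at that
#' electrode with -1 mA at the reference, from the classical concentric-
#' sphere Legendre series (superposition of the two monopole terms). En is
#' signed by the package convention: node normals point outward and
#' positive En means the field points into the cortical surface, so En
#' equals the radial potential derivative on the (radially oriented) sphere
#' normals. Cortical nodes are assumed (and checked) to lie on the sphere
#' of `spec$cortical_radius` centred at the origin.
#'
#' @param spec a [spherical_head_spec()].
#' @param surface a `cortical_surface` triangulating that sphere.
#' @param tail_tolerance relative truncation tolerance of the series
#'   (default 1e-8); an error asks for a larger `series_order` when unmet.
#' @return a [leadfield()].
#' @export
spherical_leadfield <- function(spec, surface, tail_tolerance = 1e-8) {
  stopifnot(inherits(spec, "spherical_head_spec"),
            inherits(surface, "cortical_surface"))
  r <- sqrt(rowSums(surface$nodes^2))
  if (any(abs(r / spec$cortical_radius - 1) > 1e-6))
    stop("surface nodes do not lie on the cortical sphere (radius ",
         spec$cortical_radius, " mm)")
  g <- sphere_series_coeffs(spec$shell_radii, spec$shell_conductivities,
                            spec$cortical_radius, spec$series_order)
  check_series_convergence(g, tail_tolerance)
  u <- surface$nodes / r
  pos <- spec$electrode_positions
  mono <- vapply(pos, function(p) {
    legendre_series(g, pmin(1, pmax(-1, u %*% p)))
  }, numeric(nrow(u)))
  ref <- spec$reference_label
  labs <- setdiff(names(pos), ref)
  K <- mono[, labs, drop = FALSE] - mono[, ref]
  leadfield(K, labs, ref)
}

#' Induced En of a montage
#'
#' @param m a `montage`.
#' @param subject a `subject_model`.
#' @return numeric vector of En (V/m) per cortical node.
#' @export
induced_en <- function(m, subject) {
  I <- montage_vector(m, subject$leadfield)
  as.numeric(subject$leadfield$K %*% I)
}
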