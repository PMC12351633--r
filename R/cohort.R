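#' Synthetic cohort specification
#'
#' Describes a cohort of spherical-head subjects with inter-subject
#' anatomical variability: each subject scales every shell radius of the
#' base head by an independent mean-one lognormal factor (so the stated
#' jitter is the relative standard deviation of each radius), and may
#' additionally perturb tissue conductivities the same way to emulate
#' population variability in passive electrical properties. The target is a
#' circular cortical patch: inside it the target En and weight default to
#' the conventional dose-planning values (0.25 V/m, weight 10), outside the
#' target is 0 V/m with a lower weight (default 2).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param base a [spherical_head_spec()].
#' @param radius_jitter relative s.d. of each shell radius; scalar or one
#'   value per shell. Default 0.02.
#' @param conductivity_jitter relative s.d. per tissue conductivity
#'   (default 0; set > 0 for repeated conductivity-perturbed models).
#' @param target_center unit direction of the patch centre; default the
#'   left-frontal (F3) direction, a stand-in for a left-prefrontal target.
#' @param target_angle angular patch radius in radians, in (0, pi).
#' @param target_en target En inside the patch (V/m).
#' @param target_weight weight inside the patch.
#' @param off_weight weight outside the patch.
#' @param cortex_subdivisions icosphere subdivision of the cortical
#'   evaluation surface (default 3).
#' @param wm_radius white-matter core radius (mm) of the base head, used
#'   only for tissue-volume features (the forward model merges GM and WM).
#' @param seed integer RNG seed making the cohort reproducible.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        base = spherical_head_spec(),
                        radius_jitter = 0.02,
                        conductivity_jitter = 0,
                        target_center = NULL,
                        target_angle = 0.35,
                        target_en = 0.25,
                        target_weight = 10,
                        off_weight = 2,
                        cortex_subdivisions = 3L,
                        wm_radius = 60,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, target_angle > 0, target_angle < pi,
            all(radius_jitter >= 0), all(conductivity_jitter >= 0))
  nshell <- length(base$shell_radii)
  radius_jitter <- rep_len(radius_jitter, nshell)
  conductivity_jitter <- rep_len(conductivity_jitter, nshell)
  if (is.null(target_center))
    target_center <- electrode_positions_1010("F3")[[1]]
  target_center <- target_center / sqrt(sum(target_center^2))
  structure(list(n_subjects = as.integer(n_subjects), base = base,
                 radius_jitter = radius_jitter,
                 conductivity_jitter = conductivity_jitter,
                 target_center = target_center, target_angle = target_angle,
                 target_en = target_en, target_weight = target_weight,
                 off_weight = off_weight,
                 cortex_subdivisions = as.integer(cortex_subdivisions),
                 wm_radius = wm_radius, seed = as.integer(seed)),
            class = "cohort_spec")
}

# mean-one lognormal factors with relative s.d. `rel_sd` (vectorized)
lognormal_factors <- function(rel_sd) {
  sdlog <- sqrt(log(1 + rel_sd^2))
  exp(stats::rnorm(length(rel_sd), -sdlog^2 / 2, sdlog))
}

#' Generate a synthetic cohort of subject models
#'
#' Draws per-subject shell-radius (and optionally conductivity) factors,
#' solves the spherical forward model for each subject's lead-field, builds
#' the per-subject target map on the jittered cortical sphere, and fills in
#' anatomical features (scalp geodesic perimeters and tissue volumes from a
#' labelled shell tetrahedral mesh). Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param compute_features logical; computing geodesic perimeters and mesh
#'   volumes per subject costs a few hundred milliseconds each, so
#'   optimization-only studies may switch them off.
#' @param retry_cap resample limit when jittered radii come out
#'   non-increasing (shells cross).
#' @return list of [subject_model()]s, one per subject
#'   (ids `"sub01"`, ...).
#' @export
generate_cohort <- function(spec, compute_features = TRUE, retry_cap = 100L) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- spec$base
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  # one cortical template mesh, rescaled per subject
  template <- icosphere(spec$cortex_subdivisions, radius = 1)
  subjects <- vector("list", spec$n_subjects)
  for (si in seq_len(spec$n_subjects)) {
    for (try in seq_len(retry_cap)) {
      rf <- lognormal_factors(spec$radius_jitter)
      radii <- base$shell_radii * rf
      if (all(diff(radii) > 0)) break
      if (try == retry_cap)
        stop("could not draw strictly increasing shell radii after ",
             retry_cap, " tries; lower `radius_jitter`")
    }
    cf <- lognormal_factors(spec$conductivity_jitter)
    sigmas <- base$shell_conductivities * cf
    sspec <- spherical_head_spec(
      shell_radii = radii, shell_conductivities = sigmas,
      electrode_positions = base$electrode_positions,
      cortical_radius = radii[[1]], series_order = base$series_order,
      reference_label = base$reference_label)
    surf <- template
    surf$nodes <- template$nodes * radii[[1]]
    surf$node_areas <- template$node_areas * radii[[1]]^2
    lf <- spherical_leadfield(sspec, surf)
    u <- template$nodes
    inside <- as.numeric(u %*% spec$target_center) >= cos(spec$target_angle)
    tm <- target_map(ifelse(inside, spec$target_en, 0),
                     ifelse(inside, spec$target_weight, spec$off_weight))
    feats <- NULL
    if (compute_features)
      feats <- subject_features(radii, spec$wm_radius * rf[[1]])
    subjects[[si]] <- subject_model(
      sprintf("sub%02d", si), surf, lf, tm, features = feats)
    attr(subjects[[si]], "radius_factors") <- rf
    attr(subjects[[si]], "shell_radii") <- radii
    attr(subjects[[si]], "conductivities") <- sigmas
  }
  subjects
}

# Anatomical features of one spherical subject: geodesic perimeters on the
# triangulated scalp sphere and tissue volumes from a labelled shell mesh.
subject_features <- function(radii, wm_radius,
                             scalp_subdivisions = 3L,
                             volume_subdivisions = 2L) {
  scalp <- icosphere(scalp_subdivisions, radius = radii[[length(radii)]])
  lm <- nearest_nodes(scalp, landmark_directions())
  per <- geodesic_perimeters(scalp, lm)
  mesh <- shell_tet_mesh(
    c(wm_radius, radii), c("wm", "gm", "csf", "skull", "scalp"),
    subdivisions = volume_subdivisions)
  vols <- tissue_volumes(mesh)
  anatomical_features(per, vols)
}

# save/restore global RNG state so generators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
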