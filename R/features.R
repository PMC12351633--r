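#' Assemble anatomical features for one subject
#'
#' Combines the scalp geodesic perimeters with per-tissue volumes into the
#' standard one-row feature tibble, adding the normalized variants: each
#' distance divided by the sum of the three distances, and each tissue
#' volume divided by the total tissue volume.
#'
#' @param perimeters one-row tibble from [geodesic_perimeters()].
#' @param volumes tibble from [tissue_volumes()] (columns `tissue`,
#'   `volume_mm3`).
#' @return one-row tibble with columns `axial_perimeter`,
#'   `sagittal_perimeter`, `coronal_distance`, `vol_<tissue>`, and their
#'   `_norm` counterparts.
#' @export
anatomical_features <- function(perimeters, volumes) {
  stopifnot(nrow(perimeters) == 1L)
  d <- c(perimeters$axial_perimeter, perimeters$sagittal_perimeter,
         perimeters$coronal_distance)
  if (any(d <= 0)) stop("perimeters must be positive")
  vols <- stats::setNames(volumes$volume_mm3, paste0("vol_", volumes$tissue))
  if (any(vols <= 0)) stop("tissue volumes must be positive")
  out <- tibble::tibble(
    axial_perimeter = d[1], sagittal_perimeter = d[2], coronal_distance = d[3],
    axial_perimeter_norm = d[1] / sum(d),
    sagittal_perimeter_norm = d[2] / sum(d),
    coronal_distance_norm = d[3] / sum(d))
  for (nm in names(vols)) out[[nm]] <- vols[[nm]]
  for (nm in names(vols)) out[[paste0(nm, "_norm")]] <- vols[[nm]] / sum(vols)
  out
}

#' Feature table of a cohort
#'
#' @param cohort list of `subject_model`s with features attached.
#' @return tibble, one row per subject, `subject_id` first.
#' @export
cohort_features <- function(cohort) {
  rows <- purrr::map(cohort, function(s) {
    if (is.null(s$features))
      stop("subject ", s$subject_id, " has no anatomical features")
    dplyr::bind_cols(tibble::tibble(subject_id = s$subject_id), s$features)
  })
  dplyr::bind_rows(rows)
}

#' Pairwise anatomical feature differences against a template subject
#'
#' For a designated template subject, returns one row per other subject
#' with every feature difference computed as template minus subject
#' (antisymmetric under swapping the roles). These differences are the
#' regressors used to explain cross-subject transfer of the template's
#' montage.
#'
#' @param cohort list of `subject_model`s with features.
#' @param template_id the subject id (or a standalone `subject_model`)
#'   acting as template.
#' @return tibble with `template_id`, `subject_id` and one `d_<feature>`
#'   column per feature.
#' @export
feature_diffs <- function(cohort, template_id) {
  feats <- cohort_features(cohort)
  if (inherits(template_id, "subject_model")) {
    tfeat <- dplyr::bind_cols(
      tibble::tibble(subject_id = template_id$subject_id),
      template_id$features)
    tid <- template_id$subject_id
    if (!tid %in% feats$subject_id) feats <- dplyr::bind_rows(feats, tfeat)
  } else {
    tid <- template_id
    if (!tid %in% feats$subject_id)
      stop("template subject ", tid, " not in cohort")
  }
  fcols <- setdiff(names(feats), "subject_id")
  tv <- feats[feats$subject_id == tid, fcols]
  out <- feats[feats$subject_id != tid, , drop = FALSE]
  diffs <- purrr::map_dfc(fcols, function(cn) {
    tibble::tibble(!!paste0("d_", cn) := tv[[cn]] - out[[cn]])
  })
  dplyr::bind_cols(
    tibble::tibble(template_id = tid, subject_id = out$subject_id), diffs)
}
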