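#' NERNI: normalized error relative to no intervention
#'
#' The fitness maximized during dose planning. With per-node weights `w`,
#' target field `t`, lead-field `K` and currents `I` (mA, reference
#' implicit in the bipolar column convention),
#'
#' \deqn{NERNI = \frac{\|w \odot t\|^2 - \|w \odot (K I) - w \odot t\|^2}
#'                    {\|w \odot t\|^2}}
#'
#' i.e. one minus the weighted squared misfit of the induced field, scaled
#' by the weighted squared target. It equals 1 only for a perfect fit on
#' every positively weighted node, 0 for no stimulation (`I = 0`), and is
#' unbounded below for poor fits. Weights enter inside the squared norm, so
#' the conventional target/off-target weights of 10 and 2 act with an
#' effective 25x ratio.
#'
#' @param m a `montage`.
#' @param subject a `subject_model`.
#' @return scalar NERNI (dimensionless).
#' @export
nerni <- function(m, subject) {
  stopifnot(inherits(m, "montage"), inherits(subject, "subject_model"))
  I <- montage_vector(m, subject$leadfield)
  nerni_currents(I, subject)
}

# NERNI from a bare current vector over the lead-field columns.
nerni_currents <- function(I, subject) {
  w <- subject$target$weights
  t <- subject$target$en_trg
  denom <- sum((w * t)^2)
  if (denom <= 0)
    stop("all-zero weighted target for subject ", subject$subject_id,
         ": NERNI undefined")
  en <- as.numeric(subject$leadfield$K %*% I)
  (denom - sum((w * (en - t))^2)) / denom
}

#' Group NERNI: arithmetic mean across subjects
#'
#' The group-optimization objective: the same montage evaluated on every
#' subject's own head model and target, averaged.
#'
#' @param m a `montage`.
#' @param subjects non-empty list of `subject_model`s.
#' @return scalar mean NERNI.
#' @export
nerni_group <- function(m, subjects) {
  if (!length(subjects)) stop("empty subject list")
  vals <- vapply(subjects, function(s) {
    tryCatch(nerni(m, s), error = function(e)
      stop("subject ", s$subject_id, ": ", conditionMessage(e), call. = FALSE))
  }, numeric(1))
  mean(vals)
}

#' Area-weighted mean En over the target region
#'
#' The secondary intensity metric: the surface average of the induced En
#' over the nodes of the target region (nodes with a nonzero target En),
#' weighted by the per-node areas.
#'
#' @inheritParams nerni
#' @return scalar, V/m.
#' @export
mean_en <- function(m, subject) {
  stopifnot(inherits(m, "montage"), inherits(subject, "subject_model"))
  idx <- which(subject$target$en_trg != 0)
  if (!length(idx))
    stop("subject ", subject$subject_id, " has an empty target region")
  en <- induced_en(m, subject)
  A <- subject$surface$node_areas[idx]
  sum(en[idx] * A) / sum(A)
}

#' Full montage evaluation on one subject
#'
#' @inheritParams nerni
#' @return object of class `fit_result`: list with `nerni`,
#'   `mean_en_target` (V/m) and the per-node `induced_en`.
#' @export
evaluate_montage <- function(m, subject) {
  structure(list(nerni = nerni(m, subject),
                 mean_en_target = mean_en(m, subject),
                 induced_en = induced_en(m, subject),
                 subject_id = subject$subject_id),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$subject_id, ": NERNI ",
      format(x$nerni, digits = 4), ", <En> target ",
      format(x$mean_en_target, digits = 4), " V/m\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.fit_result <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id,
                 nerni = x$nerni, mean_en = x$mean_en_target)
}

#' Write a fit-result report as JSON
#' @param x a `fit_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(x, path) {
  jsonlite::write_json(
    list(subject_id = x$subject_id, nerni = x$nerni,
         mean_en_target = x$mean_en_target,
         induced_en = x$induced_en),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
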