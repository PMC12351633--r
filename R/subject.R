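#' Lead-field matrix
#'
#' Linear map from electrode injection currents (mA) to the normal component
#' of the cortical electric field En (V/m) at every surface node. Each
#' column corresponds to a bipolar injection of +1 mA at one electrode with
#' the fixed reference (cathode, default Cz) returning -1 mA, so the
#' reference never appears as a column; the current of the reference in any
#' montage is implicitly minus the sum of the listed currents.
#'
#' @param K numeric matrix, n_nodes x n_electrodes-1 (V/m per mA).
#' @param electrode_labels character, one label per column (reference
#'   excluded).
#' @param reference_label label of the fixed reference (default `"Cz"`).
#' @return object of class `leadfield`.
#' @export
leadfield <- function(K, electrode_labels, reference_label = "Cz") {
  K <- as.matrix(K); storage.mode(K) <- "double"
  electrode_labels <- as.character(electrode_labels)
  if (ncol(K) != length(electrode_labels))
    stop("one label per lead-field column required")
  if (anyDuplicated(electrode_labels))
    stop("duplicate electrode labels")
  if (reference_label %in% electrode_labels)
    stop("reference label must not be a lead-field column")
  if (!all(is.finite(K))) stop("lead-field contains non-finite entries")
  colnames(K) <- electrode_labels
  structure(list(K = K, electrode_labels = electrode_labels,
                 reference_label = reference_label),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat("<leadfield> ", nrow(x$K), " nodes x ", ncol(x$K),
      " electrodes (reference ", x$reference_label, ")\n", sep = "")
  invisible(x)
}

#' Target En map
#'
#' Per-node target for the normal field component and nonnegative per-node
#' weights. Nodes with a nonzero target make up the target region; the
#' conventional dose-planning setup puts a target En of 0.25 V/m with
#' weight 10 on the target patch and target 0 with weight 2 elsewhere, so
#' the optimizer balances on-target intensity against off-target spread.
#'
#' @param en_trg numeric vector, target En per node (V/m).
#' @param weights numeric vector, nonnegative weight per node.
#' @return object of class `target_map`.
#' @export
target_map <- function(en_trg, weights) {
  en_trg <- as.numeric(en_trg); weights <- as.numeric(weights)
  if (length(en_trg) != length(weights))
    stop("`en_trg` and `weights` must have equal length")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (!any(weights > 0)) stop("at least one node must have positive weight")
  structure(list(en_trg = en_trg, weights = weights), class = "target_map")
}

#' Electrode montage
#'
#' Sparse assignment of currents (mA) to scalp electrodes. The reference
#' electrode is excluded: its current is defined implicitly as minus the
#' sum of the listed currents (balanced total current).
#'
#' @param currents named numeric vector, electrode label -> current (mA).
#' @return object of class `montage`.
#' @export
montage <- function(currents) {
  currents <- unlist(currents)
  if (is.null(names(currents)) || any(!nzchar(names(currents))))
    stop("`currents` must be a named vector (electrode label -> mA)")
  if (anyDuplicated(names(currents))) stop("duplicate electrode labels")
  if (!all(is.finite(currents))) stop("currents must be finite")
  structure(list(currents = currents), class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cur <- x$currents[abs(x$currents) > 1e-12]
  cat("<montage> ", length(cur), " active electrode(s); reference current ",
      format(-sum(x$currents), digits = 4), " mA\n", sep = "")
  if (length(cur))
    print(round(cur, 4))
  invisible(x)
}

#' Implicit reference current of a montage
#' @param m a `montage`.
#' @return the reference (return) current in mA, `-sum(currents)`.
#' @export
reference_current <- function(m) -sum(m$currents)

#' Montage currents as a full vector over lead-field columns
#'
#' @param m a `montage`.
#' @param lf a `leadfield`; all montage labels must be lead-field columns or
#'   the reference.
#' @return numeric vector of length `ncol(lf$K)` (reference excluded).
#' @keywords internal
montage_vector <- function(m, lf) {
  labs <- names(m$currents)
  extra <- setdiff(labs, c(lf$electrode_labels, lf$reference_label))
  if (length(extra))
    stop("montage electrode(s) not in lead-field: ",
         paste(extra, collapse = ", "))
  I <- stats::setNames(numeric(ncol(lf$K)), lf$electrode_labels)
  keep <- setdiff(labs, lf$reference_label)
  I[keep] <- m$currents[keep]
  # an explicit reference entry only shifts the implicit return; the column
  # convention already routes the balance through the reference
  I
}

#' Read / write montage files
#'
#' CSV (columns `electrode,current_mA`) and JSON (object label -> mA)
#' round-trip the sparse current assignment.
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @param m a `montage` (for writing).
#' @return `read_montage` returns a `montage`; `write_montage` returns
#'   `path` invisibly.
#' @export
read_montage <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    montage(unlist(x))
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("electrode", "current_mA") %in% names(d)))
      stop("montage CSV needs columns `electrode`, `current_mA`")
    montage(stats::setNames(d$current_mA, d$electrode))
  }
}

#' @rdname read_montage
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "montage"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(m$currents), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(
      data.frame(electrode = names(m$currents), current_mA = m$currents),
      path, row.names = FALSE)
  }
  invisible(path)
}

#' Subject head model bundle
#'
#' One subject's cortical surface, lead-field, target map, and (optionally)
#' anatomical features, under a subject id. Consistency between the
#' lead-field, the target map and the surface node count is enforced.
#'
#' @param subject_id character scalar.
#' @param surface a `cortical_surface`.
#' @param leadfield a `leadfield` with `nrow(K)` equal to the node count.
#' @param target a `target_map` of the same length.
#' @param features optional one-row tibble of anatomical features.
#' @return object of class `subject_model`.
#' @export
subject_model <- function(subject_id, surface, leadfield, target,
                          features = NULL) {
  stopifnot(inherits(surface, "cortical_surface"),
            inherits(leadfield, "leadfield"),
            inherits(target, "target_map"))
  n <- nrow(surface$nodes)
  if (nrow(leadfield$K) != n)
    stop("lead-field rows (", nrow(leadfield$K),
         ") != surface nodes (", n, ")")
  if (length(target$en_trg) != n)
    stop("target map length != surface node count")
  structure(list(subject_id = as.character(subject_id), surface = surface,
                 leadfield = leadfield, target = target, features = features),
            class = "subject_model")
}

#' @export
print.subject_model <- function(x, ...) {
  cat("<subject_model> ", x$subject_id, ": ", nrow(x$surface$nodes),
      " nodes, ", ncol(x$leadfield$K), " electrodes, ",
      sum(x$target$en_trg != 0), " target nodes\n", sep = "")
  invisible(x)
}

#' Save / load a subject model as a plain-text container
#'
#' A subject container is a directory of small text files: `nodes.tsv`,
#' `triangles.tsv`, `leadfield.tsv` (electrode labels as header), and
#' `meta.json` (subject id, reference label, target/weights, features).
#'
#' @param subject a `subject_model`.
#' @param dir directory to create/fill.
#' @return `write_subject` returns `dir` invisibly; `read_subject` a
#'   `subject_model`.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", row.names = FALSE, col.names = FALSE)
  wtsv(subject$surface$nodes, "nodes.tsv")
  wtsv(subject$surface$triangles, "triangles.tsv")
  K <- subject$leadfield$K
  utils::write.table(as.data.frame(K), file.path(dir, "leadfield.tsv"),
                     sep = "\t", row.names = FALSE, col.names = TRUE)
  meta <- list(
    subject_id = subject$subject_id,
    reference_label = subject$leadfield$reference_label,
    en_trg = subject$target$en_trg,
    weights = subject$target$weights,
    features = if (!is.null(subject$features)) as.list(subject$features))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_subject
#' @export
read_subject <- function(dir) {
  rtsv <- function(f) as.matrix(utils::read.table(file.path(dir, f),
                                                  sep = "\t", header = FALSE))
  nodes <- rtsv("nodes.tsv")
  tris <- rtsv("triangles.tsv")
  Kd <- utils::read.table(file.path(dir, "leadfield.tsv"),
                          sep = "\t", header = TRUE, check.names = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  surf <- cortical_surface(nodes, tris, orient = FALSE)
  surf$node_normals <- compute_node_normals(surf)
  surf$node_areas <- compute_node_areas(surf)
  feats <- if (!is.null(meta$features) && length(meta$features))
    tibble::as_tibble(meta$features)
  subject_model(
    meta$subject_id, surf,
    leadfield(as.matrix(Kd), colnames(Kd), meta$reference_label),
    target_map(meta$en_trg, meta$weights),
    features = feats)
}
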