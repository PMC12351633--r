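# Shared fixtures, all generated in code at test time.

# Triangulated strip with exactly n nodes (n >= 3): zigzag nodes along x
# with alternating y, consecutive triples as triangles. Cheap stand-in
# surface when only the node count matters (random lead-field tests).
strip_surface <- function(n) {
  stopifnot(n >= 3)
  nodes <- cbind(seq_len(n), rep_len(c(0, 1), n), 0)
  tris <- cbind(1:(n - 2), 2:(n - 1), 3:n)
  cortical_surface(nodes, tris)
}

# Subject with a random lead-field and a random two-level weight map, for
# objective/solver tests that do not need physical fields.
random_subject <- function(n_nodes = 20, n_electrodes = 2, seed = 1,
                           id = "toy") {
  set.seed(seed)
  surf <- strip_surface(n_nodes)
  K <- matrix(rnorm(n_nodes * n_electrodes, sd = 0.1), n_nodes)
  labs <- paste0("E", seq_len(n_electrodes))
  w <- ifelse(runif(n_nodes) < 0.25, 10, 2)
  t <- ifelse(w == 10, 0.25, 0)
  if (!any(t != 0)) { w[1] <- 10; t[1] <- 0.25 }
  subject_model(id, surf, leadfield(K, labs), target_map(t, w))
}

# Small spherical cohort at reduced cortical resolution for optimizer-heavy
# tests (162 cortical nodes); features off by default for speed.
small_cohort <- function(n = 6, seed = 7, features = FALSE, ...) {
  generate_cohort(cohort_spec(n, cortex_subdivisions = 2L, seed = seed, ...),
                  compute_features = features)
}

one_spherical_subject <- function(seed = 11, ...) {
  small_cohort(1, seed = seed, ...)[[1]]
}

# Random feasible montage over a subject's electrode set.
random_montage <- function(subject, n_active = 4, seed = 1, imax = 2,
                           total = 4) {
  set.seed(seed)
  labs <- sample(subject$leadfield$electrode_labels, n_active)
  repeat {
    I <- runif(n_active, -1, 1)
    m <- montage(setNames(I, labs))
    if (max(abs(c(I, -sum(I)))) <= imax && anodal_sum(m) <= total) return(m)
  }
}

# plain 3-vector cross product for oracle computations
vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
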