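#' Optimization configuration
#'
#' Safety and search settings for montage optimization. The defaults are
#' the conventional tES planning constraints: at most 2.0 mA at any single
#' electrode (the implicit reference included), a total injected (anodal)
#' current of at most 4.0 mA summed over all electrodes including the
#' reference, and at most eight active electrodes. The genetic-algorithm
#' settings default to a population of 3000 and termination when the best
#' objective improves by less than 1e-6 for five consecutive generations;
#' desk-scale studies typically lower `ga_population` to 50-200.
#'
#' @param max_current_per_electrode mA bound on |I| at every electrode.
#' @param max_total_injected mA bound on the summed positive (anodal)
#'   currents, reference included.
#' @param max_electrodes cap on the number of active electrodes.
#' @param ga_population GA population size.
#' @param ga_stall_tolerance minimum best-objective improvement counted as
#'   progress (NERNI units).
#' @param ga_stall_generations consecutive stalled generations before
#'   termination.
#' @param ga_max_generations hard generation cap.
#' @param tournament_size,crossover_p,mutation_rate,elitism GA operators:
#'   tournament selection size, uniform-crossover probability, per-gene
#'   mutation probability (default `2 / n_candidates`), elite count.
#' @param seed integer RNG seed.
#' @param current_tolerance currents below this (mA) count as inactive.
#' @return object of class `optimization_config`.
#' @export
optimization_config <- function(max_current_per_electrode = 2.0,
                                max_total_injected = 4.0,
                                max_electrodes = 8L,
                                ga_population = 3000L,
                                ga_stall_tolerance = 1e-6,
                                ga_stall_generations = 5L,
                                ga_max_generations = 500L,
                                tournament_size = 3L,
                                crossover_p = 0.5,
                                mutation_rate = NULL,
                                elitism = 1L,
                                seed = 1L,
                                current_tolerance = 1e-6) {
  stopifnot(max_current_per_electrode > 0, max_total_injected > 0,
            max_electrodes >= 2, ga_population >= 2,
            ga_stall_tolerance > 0, ga_stall_generations >= 1)
  structure(list(
    max_current_per_electrode = max_current_per_electrode,
    max_total_injected = max_total_injected,
    max_electrodes = as.integer(max_electrodes),
    ga_population = as.integer(ga_population),
    ga_stall_tolerance = ga_stall_tolerance,
    ga_stall_generations = as.integer(ga_stall_generations),
    ga_max_generations = as.integer(ga_max_generations),
    tournament_size = as.integer(tournament_size),
    crossover_p = crossover_p,
    mutation_rate = mutation_rate,
    elitism = as.integer(elitism),
    seed = as.integer(seed),
    current_tolerance = current_tolerance), class = "optimization_config")
}

# Precompute the group objective's quadratic form over all lead-field
# columns: NERNI_group(I) = 2 c' I - I' Q I, averaging the per-subject
# normalized forms. Subjects must share one electrode label set.
cohort_quadratic <- function(subjects) {
  labs <- subjects[[1]]$leadfield$electrode_labels
  for (s in subjects)
    if (!identical(s$leadfield$electrode_labels, labs))
      stop("subjects have mismatched electrode label sets (",
           s$subject_id, ")")
  p <- length(labs)
  Q <- matrix(0, p, p); cc <- numeric(p)
  for (s in subjects) {
    w2 <- s$target$weights^2
    t <- s$target$en_trg
    D <- sum(w2 * t^2)
    if (D <= 0) stop("subject ", s$subject_id, " has an all-zero weighted target")
    WK <- s$leadfield$K * sqrt(w2)
    Q <- Q + crossprod(WK) / D
    cc <- cc + as.numeric(crossprod(s$leadfield$K, w2 * t)) / D
  }
  list(Q = Q / length(subjects), c = cc / length(subjects), labels = labs)
}

#' Solve optimal currents for a fixed electrode subset
#'
#' Maximizes NERNI (one subject) or group NERNI (several) over the currents
#' of the given electrode subset, subject to the safety constraints: every
#' electrode current within `max_current_per_electrode` (the implicit
#' reference included), the anodal (positive) current sum over all
#' electrodes including the reference within `max_total_injected`, and the
#' balanced-current identity that the reference returns minus the sum of
#' the listed currents. The objective is a concave quadratic, so the
#' solution is the global optimum; it is found by an exact dual active-set
#' QP solve with cutting planes for the (piecewise-linear) anodal-sum
#' constraint.
#'
#' When `enforce_cap` is `TRUE` and the subset already uses
#' `max_electrodes` candidates, the equality `sum(I) = 0` is added so the
#' implicit reference stays inactive and the active-electrode budget holds.
#'
#' @param electrodes character vector of electrode labels (reference
#'   excluded), a subset of the subjects' lead-field columns.
#' @param subjects a `subject_model` or non-empty list of them.
#' @param config an [optimization_config()].
#' @param enforce_cap logical; apply the `max_electrodes` accounting rule
#'   above. Set `FALSE` for an unconstrained-cardinality reference solve.
#' @param quad optional precomputed [cohort_quadratic()] of `subjects`.
#' @return list with `currents` (named, mA), `reference_current`,
#'   `objective` (NERNI or group NERNI), `active_electrodes`.
#' @export
solve_currents <- function(electrodes, subjects, config = optimization_config(),
                           enforce_cap = TRUE, quad = NULL) {
  if (inherits(subjects, "subject_model")) subjects <- list(subjects)
  if (!length(subjects)) stop("empty subject list")
  if (!length(electrodes)) stop("empty electrode subset")
  if (is.null(quad)) quad <- cohort_quadratic(subjects)
  idx <- match(electrodes, quad$labels)
  if (anyNA(idx))
    stop("electrode(s) not in lead-field: ",
         paste(electrodes[is.na(idx)], collapse = ", "))
  balanced <- enforce_cap && length(idx) >= config$max_electrodes
  sol <- qp_currents(quad$Q[idx, idx, drop = FALSE], quad$c[idx],
                     imax = config$max_current_per_electrode,
                     total_max = config$max_total_injected,
                     balanced = balanced)
  I <- stats::setNames(sol$I, electrodes)
  list(currents = I,
       reference_current = -sum(I),
       objective = sol$objective,
       active_electrodes = electrodes[abs(I) > config$current_tolerance])
}

# Maximize 2 c'I - I'QI subject to |I_e| <= imax, |sum I| <= imax (or
# sum I = 0 when balanced), and anodal total (positive parts incl. the
# implicit reference r = -sum I) <= total_max.
#
# The anodal-sum constraint is piecewise linear: within a sign orthant
# (s = sign(I), sigma = sign(r)) it reads sum_e s_e I_e - sigma sum I
# <= 2 total_max. Two exact stages: (1) a split-variable QP
# (I = p - m, p, m >= 0, slack u >= max(r, 0)) with a tiny ridge — this
# linearizes the constraint exactly and identifies the optimal orthant;
# (2) an exact QP restricted to that orthant's closure, which contains the
# global optimum of the concave objective, iterated on the (rarely
# changing) sign pattern until stable.
qp_currents <- function(Q, cc, imax, total_max, balanced = FALSE) {
  k <- length(cc)
  ones <- rep(1, k)
  zer <- numeric(k)

  # ---- stage 1: split formulation over x = (p, m, u) -------------------
  ridge <- 1e-9 * (mean(diag(Q)) + 1)
  Dx <- rbind(cbind(2 * Q + ridge * diag(k), -2 * Q, zer),
              cbind(-2 * Q, 2 * Q + ridge * diag(k), zer),
              c(zer, zer, ridge))
  dx <- c(2 * cc, -2 * cc, 0)
  cols <- list(); bs <- numeric(0); meq <- 0L
  add <- function(col, rhs) {
    cols[[length(cols) + 1L]] <<- col
    bs <<- c(bs, rhs)
  }
  if (balanced) { add(c(ones, -ones, 0), 0); meq <- 1L }
  for (i in seq_len(k)) { e <- zer; e[i] <- 1
    add(c(e, zer, 0), 0)                       # p_i >= 0
    add(c(zer, e, 0), 0)                       # m_i >= 0
    add(c(-e, e, 0), -imax)                    # I_i >= -imax? (-(p-m) >= -imax)
    add(c(e, -e, 0), -imax)                    # I_i <= imax via (p-m) >= -imax
  }
  if (!balanced) {
    add(c(ones, -ones, 0), -imax)              # sum I >= -imax
    add(c(-ones, ones, 0), -imax)              # sum I <= imax
  }
  add(c(zer, zer, 1), 0)                       # u >= 0
  add(c(ones, -ones, 1), 0)                    # u >= sum(m) - sum(p) = r
  add(c(-ones, zer, -1), -total_max)           # sum p + u <= total_max
  sol1 <- quadprog::solve.QP(Dx, dx, do.call(cbind, cols), bs, meq)
  I <- sol1$solution[seq_len(k)] - sol1$solution[k + seq_len(k)]

  # ---- stage 2: exact orthant polish ----------------------------------
  sign_of <- function(v, tol = 1e-8) ifelse(v > tol, 1, ifelse(v < -tol, -1, 0))
  best <- NULL
  seen <- character(0)
  for (it in 1:10) {
    s <- sign_of(I); s[s == 0] <- 1
    sigma <- sign_of(-sum(I)); if (sigma == 0) sigma <- 1
    key <- paste(c(s, sigma), collapse = "")
    if (key %in% seen) break
    seen <- c(seen, key)
    A <- NULL; b2 <- numeric(0); m2 <- 0L
    addI <- function(col, rhs) { A <<- cbind(A, col); b2 <<- c(b2, rhs) }
    if (balanced) { addI(ones, 0); m2 <- 1L }
    for (i in seq_len(k)) { e <- zer; e[i] <- 1
      addI(e, -imax); addI(-e, -imax)          # boxes
      addI(s[i] * e, 0)                        # sign consistency
    }
    if (!balanced) {
      addI(ones, -imax); addI(-ones, -imax)    # reference bound
      addI(-sigma * ones, 0)                   # sigma * r >= 0
    }
    addI(-(s - sigma), -2 * total_max)         # anodal sum in this orthant
    sol2 <- qp_solve_pd(2 * Q, 2 * cc, A, b2, m2)
    I2 <- sol2$solution
    obj2 <- 2 * sum(cc * I2) - as.numeric(t(I2) %*% Q %*% I2)
    if (is.null(best) || obj2 > best$objective + 1e-12)
      best <- list(I = I2, objective = obj2)
    if (identical(sign_of(I2), sign_of(I))) break
    I <- I2
  }
  anodal <- sum(pmax(best$I, 0)) + max(-sum(best$I), 0)
  if (anodal > total_max + 1e-7 ||
        max(abs(best$I), abs(sum(best$I))) > imax + 1e-7)
    stop("current solver returned an infeasible point (anodal ",
         format(anodal, digits = 8), " mA); please report")
  best
}

# quadprog::solve.QP with a graceful ridge fallback for numerically
# semidefinite objectives (e.g. near-duplicate lead-field columns).
qp_solve_pd <- function(Dmat, dvec, A, b, meq) {
  tryCatch(
    quadprog::solve.QP(Dmat, dvec, A, b, meq),
    error = function(e) {
      ridge <- 1e-10 * (mean(diag(Dmat)) + 1) * diag(nrow(Dmat))
      quadprog::solve.QP(Dmat + ridge, dvec, A, b, meq)
    })
}
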