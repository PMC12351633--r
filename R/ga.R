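#' Genetic-algorithm electrode-subset optimization
#'
#' Outer combinatorial search over electrode subsets with an exact inner
#' current solve per subset. Individuals are binary masks over the
#' candidate labels repaired to exactly `min(max_electrodes, n_candidates)`
#' active genes; fitness is the [solve_currents()] objective (NERNI or
#' group NERNI), memoized per subset. Selection is tournament
#' (size `config$tournament_size`), crossover uniform, mutation per-gene,
#' with elitism. The search stops when the best objective has improved by
#' less than `ga_stall_tolerance` for `ga_stall_generations` consecutive
#' generations (or at `ga_max_generations`). Reproducible for a fixed
#' `config$seed`; equal-objective subsets are tie-broken toward the
#' lexicographically smallest label set.
#'
#' @param subjects a `subject_model` or list of them (group objective is
#'   the arithmetic-mean NERNI).
#' @param candidates candidate electrode labels (default: all lead-field
#'   columns of the first subject).
#' @param config an [optimization_config()].
#' @return object of class `optimization_result`: `montage`, `objective`,
#'   `generations_run`, `history` (best objective per generation),
#'   `active_electrodes`, `config`.
#' @export
ga_optimize <- function(subjects, candidates = NULL,
                        config = optimization_config()) {
  if (inherits(subjects, "subject_model")) subjects <- list(subjects)
  if (!length(subjects)) stop("empty subject list")
  quad <- cohort_quadratic(subjects)
  if (is.null(candidates)) candidates <- quad$labels
  candidates <- as.character(candidates)
  if (length(candidates) < 2) stop("need at least 2 candidate electrodes")
  if (!all(candidates %in% quad$labels))
    stop("candidate(s) not in lead-field: ",
         paste(setdiff(candidates, quad$labels), collapse = ", "))
  nc <- length(candidates)
  k <- min(config$max_electrodes, nc)

  cache <- new.env(hash = TRUE, parent = emptyenv())
  eval_subset <- function(mask) {
    idx <- which(mask)
    key <- paste(idx, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    sol <- solve_currents(candidates[idx], subjects, config,
                          enforce_cap = TRUE, quad = quad)
    cache[[key]] <- sol
    sol
  }

  # degenerate search space: the full candidate set dominates all subsets
  if (nc <= config$max_electrodes) {
    sol <- eval_subset(rep(TRUE, nc))
    return(new_optimization_result(sol, candidates, 0L, sol$objective, config))
  }

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  pop_n <- config$ga_population
  mut_p <- if (is.null(config$mutation_rate)) 2 / nc else config$mutation_rate

  repair <- function(mask) {
    on <- which(mask)
    if (length(on) > k) mask[sample(on, length(on) - k)] <- FALSE
    else if (length(on) < k) {
      off <- which(!mask)
      mask[sample(off, k - length(on))] <- TRUE
    }
    mask
  }
  pop <- t(vapply(seq_len(pop_n), function(i) {
    m <- rep(FALSE, nc); m[sample(nc, k)] <- TRUE; m
  }, logical(nc)))

  best_obj <- -Inf; best_sol <- NULL; best_mask <- NULL
  history <- numeric(0)
  stall <- 0L
  gens <- 0L
  lex_smaller <- function(a, b) {
    # TRUE if label set a precedes label set b lexicographically
    la <- sort(candidates[a]); lb <- sort(candidates[b])
    d <- which(la != lb)
    if (!length(d)) FALSE else la[d[1]] < lb[d[1]]
  }

  repeat {
    gens <- gens + 1L
    fit <- vapply(seq_len(pop_n),
                  function(i) eval_subset(pop[i, ])$objective, numeric(1))
    gi <- which(fit == max(fit))
    # deterministic tie-break within the generation
    gbi <- gi[[1L]]
    for (cand in gi[-1L])
      if (lex_smaller(pop[cand, ], pop[gbi, ])) gbi <- cand
    improved <- fit[gbi] > best_obj + config$ga_stall_tolerance
    if (fit[gbi] > best_obj ||
          (fit[gbi] == best_obj && !is.null(best_mask) &&
             lex_smaller(pop[gbi, ], best_mask))) {
      best_obj <- fit[gbi]
      best_mask <- pop[gbi, ]
      best_sol <- eval_subset(best_mask)
    }
    history <- c(history, best_obj)
    stall <- if (improved) 0L else stall + 1L
    if (stall >= config$ga_stall_generations ||
          gens >= config$ga_max_generations) break

    # next generation: elitism + tournament/crossover/mutation
    newpop <- matrix(FALSE, pop_n, nc)
    ne <- min(config$elitism, pop_n)
    if (ne > 0) newpop[seq_len(ne), ] <- matrix(best_mask, ne, nc, byrow = TRUE)
    tourney <- function() {
      cont <- sample.int(pop_n, config$tournament_size, replace = TRUE)
      cont[which.max(fit[cont])]
    }
    for (i in seq.int(ne + 1L, pop_n)) {
      p1 <- pop[tourney(), ]; p2 <- pop[tourney(), ]
      swap <- stats::runif(nc) < config$crossover_p
      child <- ifelse(swap, p2, p1)
      flip <- stats::runif(nc) < mut_p
      child[flip] <- !child[flip]
      newpop[i, ] <- repair(child)
    }
    pop <- newpop
  }
  new_optimization_result(best_sol, candidates[which(best_mask)],
                          gens, history, config)
}

new_optimization_result <- function(sol, subset, generations, history,
                                    config) {
  structure(list(
    montage = montage(sol$currents),
    objective = sol$objective,
    generations_run = generations,
    history = history,
    active_electrodes = sol$active_electrodes,
    subset = subset,
    config = config), class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("<optimization_result> objective ", format(x$objective, digits = 6),
      ", ", length(x$active_electrodes), " active electrode(s), ",
      x$generations_run, " generation(s)\n", sep = "")
  print(x$montage)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.optimization_result <- function(x, ...) {
  cur <- x$montage$currents
  tibble::tibble(electrode = c(names(cur), "(reference)"),
                 current_mA = c(unname(cur), -sum(cur)),
                 active = c(abs(cur), abs(sum(cur))) >
                   x$config$current_tolerance)
}

#' @exportS3Method generics::glance
glance.optimization_result <- function(x, ...) {
  tibble::tibble(objective = x$objective,
                 n_active = length(x$active_electrodes),
                 generations_run = x$generations_run,
                 anodal_sum_mA = anodal_sum(x$montage),
                 max_abs_current_mA = max(abs(c(x$montage$currents,
                                                -sum(x$montage$currents)))))
}

#' Anodal (total injected) current of a montage
#'
#' Sum of the positive currents over all electrodes, the implicit
#' reference included.
#' @param m a `montage`.
#' @return mA.
#' @export
anodal_sum <- function(m) {
  sum(pmax(m$currents, 0)) + max(-sum(m$currents), 0)
}

#' Check a montage against the safety constraint suite
#'
#' @param m a `montage`.
#' @param config an [optimization_config()].
#' @param tol slack on the current bounds (mA).
#' @return `TRUE` invisibly; errors describing every violated constraint
#'   otherwise.
#' @export
validate_montage <- function(m, config = optimization_config(), tol = 1e-6) {
  cur_all <- c(m$currents, reference = -sum(m$currents))
  bad <- character(0)
  if (max(abs(cur_all)) > config$max_current_per_electrode + tol)
    bad <- c(bad, sprintf("max |I| = %.6f mA exceeds %g mA",
                          max(abs(cur_all)), config$max_current_per_electrode))
  if (anodal_sum(m) > config$max_total_injected + tol)
    bad <- c(bad, sprintf("anodal sum = %.6f mA exceeds %g mA",
                          anodal_sum(m), config$max_total_injected))
  n_active <- sum(abs(cur_all) > config$current_tolerance)
  if (n_active > config$max_electrodes)
    bad <- c(bad, sprintf("%d active electrodes exceed the cap of %d",
                          n_active, config$max_electrodes))
  if (length(bad)) stop("montage violates constraints:\n  ",
                        paste(bad, collapse = "\n  "))
  invisible(TRUE)
}

#' Leave-one-out group optimization over a cohort
#'
#' For every subject, runs the group GA on the remaining subjects and
#' evaluates the resulting montage on the held-out subject. Each
#' leave-one-out run uses its own derived seed, so the group montages are
#' independent searches.
#'
#' @param cohort list of `subject_model`s (>= 2).
#' @param config an [optimization_config()].
#' @param candidates candidate labels (default all lead-field columns).
#' @return named list (by held-out subject id) of `optimization_result`s,
#'   each augmented with `held_out`, a one-row tibble of the held-out
#'   subject's `nerni` and `mean_en` under the group montage.
#' @export
optimize_group_loo <- function(cohort, config = optimization_config(),
                               candidates = NULL) {
  if (length(cohort) < 2) stop("leave-one-out needs a cohort of >= 2")
  ids <- vapply(cohort, function(s) s$subject_id, character(1))
  out <- vector("list", length(cohort))
  names(out) <- ids
  for (i in seq_along(cohort)) {
    cfg <- config
    cfg$seed <- config$seed + i
    res <- ga_optimize(cohort[-i], candidates = candidates, config = cfg)
    held <- cohort[[i]]
    res$held_out <- tibble::tibble(
      subject_id = held$subject_id,
      nerni = nerni(res$montage, held),
      mean_en = mean_en(res$montage, held))
    out[[i]] <- res
  }
  out
}
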