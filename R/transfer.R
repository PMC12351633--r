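#' Assemble a protocol set for transfer evaluation
#'
#' Bundles montages with their protocol kind and, for subject-bound kinds,
#' the subject they belong to. Kinds follow the four-way comparison design:
#' `personalized` (optimized on and evaluated in the same subject),
#' `group_loo` (optimized on everyone else, evaluated in the held-out
#' subject), `template` (montage from a designated template head model,
#' evaluated in everyone), and `non_personalized_individual` (montage from
#' one cohort member's head model, evaluated in everyone).
#'
#' @param personalized named list (subject_id -> `montage` or
#'   `optimization_result`).
#' @param group_loo named list (held-out subject_id -> montage/result).
#' @param templates named list (protocol_id -> montage/result).
#' @param individual named list (source subject_id -> montage/result);
#'   protocol ids become `"non_pers_<id>"`.
#' @return tibble with columns `protocol_id`, `kind`, `own_subject`,
#'   `montage` (list-column).
#' @export
protocol_set <- function(personalized = NULL, group_loo = NULL,
                         templates = NULL, individual = NULL) {
  as_mont <- function(x)
    if (inherits(x, "optimization_result")) x$montage else x
  rows <- list()
  add <- function(lst, kind, id_fmt = identity, own = TRUE) {
    if (is.null(lst)) return()
    for (nm in names(lst)) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        protocol_id = id_fmt(nm), kind = kind,
        own_subject = if (own) nm else NA_character_,
        montage = list(as_mont(lst[[nm]])))
    }
  }
  add(personalized, "personalized", function(nm) paste0("pers_", nm))
  add(group_loo, "group_loo", function(nm) paste0("group_loo_", nm))
  add(templates, "template", own = FALSE)
  add(individual, "non_personalized_individual",
      function(nm) paste0("non_pers_", nm))   # own = source head model
  if (!length(rows)) stop("no protocols supplied")
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$protocol_id)) stop("duplicate protocol ids")
  out
}

#' Evaluate protocols across a cohort (transfer table)
#'
#' Crosses protocols with subjects and computes NERNI and the target-region
#' mean En for every applicable pair: subject-bound protocols
#' (`personalized`, `group_loo`) are evaluated only in their own subject,
#' template and non-personalized-individual protocols in every subject
#' (the latter skipping their source subject, where they would be
#' personalized). Evaluation failures (e.g. electrode label mismatches) are
#' recorded per pair in the `error` column instead of aborting the table.
#'
#' @param protocols tibble from [protocol_set()] (or a named list of
#'   montages, treated as templates).
#' @param cohort list of `subject_model`s.
#' @return a transfer table: tibble with `subject_id`, `protocol_id`,
#'   `protocol_kind`, `nerni`, `mean_en`, `error`.
#' @export
evaluate_transfer <- function(protocols, cohort) {
  if (!inherits(protocols, "data.frame"))
    protocols <- protocol_set(templates = protocols)
  ids <- vapply(cohort, function(s) s$subject_id, character(1))
  rows <- list()
  for (pi in seq_len(nrow(protocols))) {
    kind <- protocols$kind[[pi]]
    own <- protocols$own_subject[[pi]]
    m <- protocols$montage[[pi]]
    targets <- if (kind %in% c("personalized", "group_loo")) {
      if (is.na(own) || !own %in% ids)
        stop("protocol ", protocols$protocol_id[[pi]],
             " is subject-bound but its subject is not in the cohort")
      own
    } else if (kind == "non_personalized_individual" && !is.na(own)) {
      setdiff(ids, own)
    } else ids
    for (sid in targets) {
      s <- cohort[[match(sid, ids)]]
      res <- tryCatch(
        list(nerni = nerni(m, s), mean_en = mean_en(m, s), err = NA_character_),
        error = function(e) list(nerni = NA_real_, mean_en = NA_real_,
                                 err = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sid, protocol_id = protocols$protocol_id[[pi]],
        protocol_kind = kind, nerni = res$nerni, mean_en = res$mean_en,
        error = res$err)
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$subject_id, .data$protocol_id)
}

# condition label used for within-subject comparisons: subject-bound kinds
# collapse to their kind (one value per subject), others stay per-protocol
transfer_condition <- function(table) {
  dplyr::mutate(table, condition = ifelse(
    .data$protocol_kind %in% c("personalized", "group_loo"),
    .data$protocol_kind, .data$protocol_id))
}

#' Statistical comparison of protocol conditions
#'
#' Reproduces the two-track comparison plan on a transfer table: (1)
#' within-subject pairwise paired t-tests between conditions with
#' Bonferroni adjustment over the number of pairs, honouring the
#' repeated-measures design; (2) a nonparametric Kruskal-Wallis test across
#' conditions followed by Dunn post-hoc pairwise z-tests (mid-ranks,
#' tie-corrected) with Bonferroni adjustment. Subject-bound protocol kinds
#' (personalized, group-LOO) form one condition each; template and
#' individual-derived protocols are conditions of their own.
#'
#' @param table a transfer table from [evaluate_transfer()].
#' @param metric `"nerni"` (default) or `"mean_en"`.
#' @return object of class `protocol_comparison`: list with
#'   `paired_tests`, `kruskal` (statistic, df, p), `dunn` (pairwise
#'   tibble), `summary` (per-condition mean, sd, n).
#' @export
compare_protocols <- function(table, metric = c("nerni", "mean_en")) {
  metric <- match.arg(metric)
  d <- transfer_condition(table)
  d <- d[!is.na(d[[metric]]), c("subject_id", "condition", metric)]
  names(d)[3] <- "value"
  conds <- sort(unique(d$condition))
  if (length(conds) < 2) stop("need >= 2 protocol conditions")
  if (length(unique(d$subject_id)) < 3) stop("need >= 3 subjects")
  wide <- tidyr::pivot_wider(d, names_from = "condition",
                             values_from = "value")
  gaps <- which(is.na(as.matrix(wide[conds])), arr.ind = TRUE)
  if (nrow(gaps))
    stop("incomplete subject x condition crossing for paired tests: ",
         paste(utils::head(sprintf("(%s, %s)", wide$subject_id[gaps[, 1]],
                                   conds[gaps[, 2]]), 5L), collapse = ", "))

  pairs <- utils::combn(conds, 2)
  m <- ncol(pairs)
  paired <- purrr::map_dfr(seq_len(m), function(j) {
    a <- wide[[pairs[1, j]]]; b <- wide[[pairs[2, j]]]
    dif <- a - b
    if (stats::sd(dif) < 1e-14) {
      # degenerate paired data: identical conditions give t = 0, p = 1;
      # an exactly constant nonzero shift is infinitely significant
      tstat <- if (abs(mean(dif)) < 1e-14) 0 else sign(mean(dif)) * Inf
      pval <- if (tstat == 0) 1 else 0
      dfree <- length(dif) - 1
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      tstat <- unname(tt$statistic); pval <- tt$p.value
      dfree <- unname(tt$parameter)
    }
    tibble::tibble(condition_a = pairs[1, j], condition_b = pairs[2, j],
                   mean_diff = mean(dif),
                   t_statistic = tstat, df = dfree, p_value = pval)
  })
  paired$p_adjusted <- pmin(1, paired$p_value * m)

  kw <- stats::kruskal.test(d$value, factor(d$condition))
  dunn <- dunn_test(d$value, factor(d$condition))

  summary <- dplyr::summarise(
    dplyr::group_by(d, .data$condition),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    n = dplyr::n(), .groups = "drop")

  structure(list(metric = metric, paired_tests = paired,
                 kruskal = tibble::tibble(
                   statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p_value = kw$p.value),
                 dunn = dunn, summary = summary),
            class = "protocol_comparison")
}

# Dunn's post-hoc test from joint mid-ranks with tie correction and
# Bonferroni adjustment; large-sample z approximation.
dunn_test <- function(values, groups) {
  N <- length(values)
  r <- rank(values)                       # mid-ranks
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  g <- names(rbar)
  pairs <- utils::combn(g, 2)
  m <- ncol(pairs)
  purrr::map_dfr(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[i1]] + 1 / n[[i2]]))
    z <- (rbar[[i1]] - rbar[[i2]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(condition_a = i1, condition_b = i2, z = z,
                   p_value = p, p_adjusted = min(1, p * m))
  })
}

#' @export
print.protocol_comparison <- function(x, ...) {
  cat("<protocol_comparison> metric:", x$metric, "\n")
  cat("Kruskal-Wallis H =", format(x$kruskal$statistic, digits = 4),
      ", df =", x$kruskal$df,
      ", p =", format(x$kruskal$p_value, digits = 3), "\n")
  cat("Per-condition summary:\n")
  print(x$summary)
  cat("Paired t-tests (Bonferroni-adjusted):\n")
  print(x$paired_tests)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.protocol_comparison <- function(x, ...) x$paired_tests

#' @exportS3Method generics::glance
glance.protocol_comparison <- function(x, ...) {
  tibble::tibble(metric = x$metric,
                 kruskal_statistic = x$kruskal$statistic,
                 kruskal_df = x$kruskal$df, kruskal_p = x$kruskal$p_value,
                 n_conditions = nrow(x$summary))
}

#' Quadratic fit of NERNI against target mean En
#'
#' Ordinary least squares of NERNI on (1, <En>, <En>^2) over all rows of a
#' transfer table, the global relationship showing that both very low and
#' very high target intensities yield poor fits.
#'
#' @param table a transfer table (or any tibble with `nerni` and `mean_en`).
#' @return list with `coefficients` (tibble: term, estimate, std_error,
#'   p_value), `r_squared`, `model` (the `lm` fit).
#' @export
nerni_vs_mean_en_fit <- function(table) {
  d <- table[!is.na(table$nerni) & !is.na(table$mean_en), ]
  if (length(unique(d$mean_en)) < 3)
    stop("need >= 3 distinct mean_en values for a quadratic fit")
  fit <- stats::lm(nerni ~ mean_en + I(mean_en^2), data = d)
  if (fit$rank < 3) stop("rank-deficient quadratic design")
  s <- summary(fit)
  co <- s$coefficients
  list(coefficients = tibble::tibble(
    term = c("intercept", "mean_en", "mean_en^2"),
    estimate = co[, 1], std_error = co[, 2], p_value = co[, 4]),
    r_squared = s$r.squared, model = fit)
}

#' Write a transfer table / comparison report
#' @param table transfer table.
#' @param path output path (TSV for tables, JSON for comparisons).
#' @export
write_transfer_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param x a `protocol_comparison`.
#' @rdname write_transfer_table
#' @export
write_comparison_report <- function(x, path) {
  jsonlite::write_json(
    list(metric = x$metric, paired_tests = x$paired_tests,
         kruskal = x$kruskal, dunn = x$dunn, summary = x$summary),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
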