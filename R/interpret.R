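#' PC-outcome association heatmap
#'
#' For each binary outcome (a cause of death within a follow-up window, a
#' chronic-disease flag, or a sociological factor), fits one multivariate
#' logistic regression with all supplied PC scores as simultaneous
#' covariates, then applies the display truncation rules: coefficients
#' with p >= `p_cut` are set to zero (`zeroed_by_p`); in
#' `"cause_of_death"` mode, negative coefficients are additionally set to
#' zero (`truncated_negative` — "no harm"); in `"disease_or_social"` mode
#' signed values are retained, clipped for display to `clip`. Raw
#' coefficients, SEs and p-values are always kept alongside the truncated
#' display matrix. Fits are per sex: pass one sex's scores at a time.
#'
#' @param scores A numeric matrix/data.frame of PC scores (subjects x
#'   components) for a single sex.
#' @param outcomes A data.frame of binary (0/1 or logical) outcome columns
#'   aligned row-wise with `scores`.
#' @param mode Truncation mode.
#' @param p_cut Per-cell significance threshold (raw, no multiplicity
#'   correction by default, matching the display rule).
#' @param clip Display clip range for `"disease_or_social"` mode.
#' @param adjust Optional p-value adjustment method across the heatmap's
#'   cells (`"none"` default, or any [stats::p.adjust()] method).
#' @return An object of class `"heatmap_matrix"`: the displayed matrix
#'   (outcomes x components) with a long-format `data.frame` in attribute
#'   `"table"` (`outcome`, `component`, `raw_coef`, `se`, `p`,
#'   `displayed`, `provenance`).
#' @export
pc_outcome_heatmap <- function(scores, outcomes,
                               mode = c("cause_of_death",
                                        "disease_or_social"),
                               p_cut = 0.05, clip = c(-1, 2),
                               adjust = "none") {
  mode <- match.arg(mode)
  X <- as.matrix(scores)
  if (!is.numeric(X)) stop("scores must be numeric")
  stopifnot(nrow(X) == nrow(outcomes))
  comps <- colnames(X)
  if (is.null(comps)) comps <- paste0("PC", seq_len(ncol(X)))
  rows <- list()
  for (oc in names(outcomes)) {
    y <- as.numeric(outcomes[[oc]])
    keep <- !is.na(y) & stats::complete.cases(X)
    df <- data.frame(.y = y[keep], X[keep, , drop = FALSE],
                     check.names = FALSE)
    fit <- tryCatch(
      suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(),
                                  data = df)),
      error = function(e) NULL)
    if (is.null(fit)) {
      rows[[oc]] <- data.frame(outcome = oc, component = comps,
                               raw_coef = NA_real_, se = NA_real_,
                               p = NA_real_, stringsAsFactors = FALSE)
      next
    }
    sm <- summary(fit)$coefficients
    # drop intercept; align to component order
    cf <- sm[-1, , drop = FALSE]
    rn <- sub("^`|`$", "", rownames(cf))
    rn <- gsub("`", "", rn)
    raw <- se <- p <- rep(NA_real_, length(comps))
    mi <- match(comps, rn)
    ok <- !is.na(mi)
    raw[ok] <- cf[mi[ok], "Estimate"]
    se[ok] <- cf[mi[ok], "Std. Error"]
    p[ok] <- cf[mi[ok], "Pr(>|z|)"]
    # separation / non-convergence: huge coefficients or SEs are unstable;
    # flag by giving them p = 1 so the display zeroes them
    unstable <- ok & (abs(raw) > 15 | se > 15 | !is.finite(se))
    if (any(unstable)) {
      warning("unstable logistic coefficient(s) for outcome '", oc,
              "' (possible separation); zeroed in the display")
      p[unstable] <- 1
    }
    rows[[oc]] <- data.frame(outcome = oc, component = comps,
                             raw_coef = raw, se = se, p = p,
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (adjust != "none") tab$p <- stats::p.adjust(tab$p, method = adjust)
  insignif <- is.na(tab$p) | tab$p >= p_cut
  tab$displayed <- ifelse(insignif, 0, tab$raw_coef)
  tab$provenance <- ifelse(insignif, "zeroed_by_p", "significant")
  if (mode == "cause_of_death") {
    neg <- !insignif & tab$raw_coef < 0
    tab$displayed[neg] <- 0
    tab$provenance[neg] <- "truncated_negative"
  } else {
    tab$displayed <- pmin(pmax(tab$displayed, clip[1]), clip[2])
  }
  M <- matrix(tab$displayed, nrow = length(rows), byrow = TRUE,
              dimnames = list(names(rows), comps))
  structure(M, table = tab, mode = mode, p_cut = p_cut,
            class = c("heatmap_matrix", "matrix"))
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat("PC-outcome heatmap (", attr(x, "mode"), " mode, p < ",
      attr(x, "p_cut"), ")\n", sep = "")
  print(round(unclass(x)[, , drop = FALSE], 3))
  invisible(x)
}

#' Per-subject PC contribution report
#'
#' Decomposes a scored subject's age delta into per-PC year contributions
#' (PC score times Cox weight, divided by the Gompertz slope), ordered by
#' magnitude, and, for each PC contributing at least `min_years` years in
#' either direction, lists the clinical parameters with |loading| >=
#' `loading_threshold` together with the subject's raw values — the
#' actionable view of why the clock aged this subject.
#'
#' @param result A [predict.pcclock()] result.
#' @param clock The `"pcclock"` object that produced it.
#' @param id Subject id to report.
#' @param cohort Optional cohort table; supplies raw parameter values.
#' @param loading_threshold Minimum |loading| for a parameter to be listed.
#' @param min_years Minimum |contribution| (years) for a PC to be expanded.
#' @return A list of class `"subject_report"`: `id`, `chron_age`,
#'   `biological_age`, `delta`, `centering_term`, `contributions` (named,
#'   years, sorted by |value|), and `drivers` — per flagged PC, a
#'   `data.frame` of parameter, loading, and (if available) the subject's
#'   raw value.
#' @export
subject_report <- function(result, clock, id, cohort = NULL,
                           loading_threshold = 0.1, min_years = 1) {
  stopifnot(inherits(result, "ba_result"), inherits(clock, "pcclock"))
  i <- match(id, result$id)
  if (is.na(i)) stop("subject '", id, "' not found in the scored results")
  contrib <- attr(result, "contributions")[i, ]
  contrib <- contrib[!is.na(contrib)]
  contrib <- contrib[order(-abs(contrib))]
  flagged <- names(contrib)[abs(contrib) >= min_years]
  sex <- result$sex[i]
  loadings <- clock$factor_model$by_sex[[sex]]$loadings
  drivers <- list()
  for (cp in flagged) {
    l <- loadings[, cp]
    sel <- abs(l) >= loading_threshold
    d <- data.frame(parameter = names(l)[sel], loading = unname(l[sel]),
                    stringsAsFactors = FALSE)
    d <- d[order(-abs(d$loading)), , drop = FALSE]
    if (!is.null(cohort)) {
      j <- match(id, cohort$id)
      d$value <- vapply(d$parameter, function(pp)
        as.numeric(cohort[[pp]][j]), numeric(1))
    }
    rownames(d) <- NULL
    drivers[[cp]] <- d
  }
  structure(list(id = id, sex = sex, chron_age = result$chron_age[i],
                 biological_age = result$biological_age[i],
                 delta = result$delta[i],
                 centering_term = result$centering_term[i],
                 contributions = contrib, drivers = drivers,
                 loading_threshold = loading_threshold),
            class = "subject_report")
}

#' @export
print.subject_report <- function(x, ...) {
  cat(sprintf("Subject %s (%s): CA %.1f y, BA %.1f y (delta %+.1f y)\n",
              x$id, x$sex, x$chron_age, x$biological_age, x$delta))
  cat("Per-PC contributions (years; + = older):\n")
  print(round(x$contributions, 2))
  for (cp in names(x$drivers)) {
    cat(sprintf("\n%s drivers (|loading| >= %g):\n", cp,
                x$loading_threshold))
    print(x$drivers[[cp]], row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Healthspan markers from questionnaire and exam fields
#'
#' Builds the standard functional-aging markers: the raw
#' digit-symbol-substitution cognitive score; gait speed as the walk
#' distance (default 6.096 m, i.e. 20 feet) divided by the timed-walk
#' seconds; ability to work; and the instrumental/basic
#' activities-of-daily-living composites — a subject is "able" only if
#' every item in the set is at worst "some difficulty". A missing (or, for
#' walk time, non-positive) input leaves the marker missing.
#'
#' @param cohort A cohort `data.frame`.
#' @param iadl_items,badl_items Names of the ADL item columns (defaults
#'   match [simulate_cohort()]: 6 instrumental, 7 basic).
#' @param walk_distance Walk-course length in meters.
#' @return A `data.frame`: `id`, `cognitive`, `gait_speed` (m/s),
#'   `work_able`, `iadl_able`, `badl_able` (logical or NA).
#' @export
healthspan_markers <- function(cohort, iadl_items = paste0("adl_i", 1:6),
                               badl_items = paste0("adl_b", 1:7),
                               walk_distance = 6.096) {
  validate_cohort(cohort)
  n <- nrow(cohort)
  gait <- rep(NA_real_, n)
  if ("walk_time" %in% names(cohort)) {
    wt <- cohort$walk_time
    bad <- !is.na(wt) & wt <= 0
    if (any(bad)) warning(sum(bad), " non-positive walk time(s); ",
                          "gait speed left missing")
    ok <- !is.na(wt) & wt > 0
    gait[ok] <- walk_distance / wt[ok]
  }
  able_set <- c("no difficulty", "some difficulty")
  composite <- function(items) {
    items <- intersect(items, names(cohort))
    if (length(items) == 0L) return(rep(NA, n))
    M <- sapply(items, function(it) cohort[[it]])
    M <- matrix(as.character(M), nrow = n)
    apply(M, 1L, function(r) {
      if (anyNA(r)) NA else all(r %in% able_set)
    })
  }
  data.frame(
    id = cohort$id,
    cognitive = if ("dsst_score" %in% names(cohort))
      cohort$dsst_score else NA_real_,
    gait_speed = gait,
    work_able = if ("work_able" %in% names(cohort))
      ifelse(is.na(cohort$work_able), NA, cohort$work_able == "yes")
    else NA,
    iadl_able = composite(iadl_items),
    badl_able = composite(badl_items),
    stringsAsFactors = FALSE)
}

#' Compare clock ages (or any marker) between two groups
#'
#' Two-sided two-sample comparison of a numeric variable between two
#' groups (e.g. lowest- vs highest-quartile clock age, able vs unable),
#' by Welch t-test or Wilcoxon rank-sum test. When `control` values are
#' supplied (e.g. the middle 50% of all subjects), each group's percent
#' difference from the control mean is reported.
#'
#' @param values Numeric vector.
#' @param group Two-level factor/character/logical of the same length.
#' @param test `"t_test"` or `"wilcoxon"`.
#' @param control Optional numeric vector of control-group values.
#' @return A one-row `data.frame`: group labels and sizes, means, medians,
#'   statistic, `p`, and (with `control`) `pct_diff_1`, `pct_diff_2`.
#' @export
group_compare <- function(values, group, test = c("t_test", "wilcoxon"),
                          control = NULL) {
  test <- match.arg(test)
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- as.character(group[keep])
  lev <- unique(group)
  if (length(lev) != 2L) stop("group must have exactly 2 levels")
  g1 <- values[group == lev[1]]; g2 <- values[group == lev[2]]
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("both groups need at least 2 subjects")
  }
  ht <- if (test == "t_test") stats::t.test(g1, g2)
  else stats::wilcox.test(g1, g2, exact = FALSE)
  out <- data.frame(
    group_1 = lev[1], group_2 = lev[2],
    n_1 = length(g1), n_2 = length(g2),
    mean_1 = mean(g1), mean_2 = mean(g2),
    median_1 = stats::median(g1), median_2 = stats::median(g2),
    statistic = unname(ht$statistic), p = ht$p.value,
    test = test, stringsAsFactors = FALSE)
  if (!is.null(control)) {
    cm <- mean(control, na.rm = TRUE)
    out$pct_diff_1 <- 100 * (mean(g1) - cm) / cm
    out$pct_diff_2 <- 100 * (mean(g2) - cm) / cm
  }
  out
}
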