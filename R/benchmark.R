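#' Binary k-year mortality labels
#'
#' Labels each subject for a k-year mortality horizon: `died_within` if the
#' subject died at or before the horizon, `survived_beyond` if observed
#' (dead or alive) past it, and `excluded_censored` if censored before the
#' horizon — such subjects carry no usable binary label and are excluded
#' from ROC analyses (simple-exclusion convention; no censoring weights).
#'
#' @param cohort A cohort `data.frame`.
#' @param horizon Horizon in years (> 0).
#' @return A character vector of class `"mortality_label"` with attribute
#'   `"counts"` and `"horizon"`.
#' @export
mortality_labels <- function(cohort, horizon) {
  validate_cohort(cohort)
  stopifnot(horizon > 0)
  lab <- ifelse(cohort$event == "died" & cohort$follow_up_time <= horizon,
                "died_within",
         ifelse(cohort$event == "censored" & cohort$follow_up_time < horizon,
                "excluded_censored", "survived_beyond"))
  counts <- c(died_within = sum(lab == "died_within"),
              survived_beyond = sum(lab == "survived_beyond"),
              excluded_censored = sum(lab == "excluded_censored"))
  if (counts[["died_within"]] == 0L || counts[["survived_beyond"]] == 0L) {
    stop("AUC undefined at horizon ", horizon,
         ": need at least one death and one survivor after censoring ",
         "exclusion")
  }
  structure(lab, counts = counts, horizon = horizon,
            names = cohort$id, class = "mortality_label")
}

#' Mann-Whitney AUC for k-year mortality
#'
#' The probability that a randomly chosen subject who died within the
#' horizon scores higher than a randomly chosen survivor, with ties counted
#' half (midrank estimator). Censored-before-horizon subjects are omitted.
#'
#' @param scores Per-subject risk scores (higher = riskier), aligned with
#'   `labels`.
#' @param labels A [mortality_labels()] vector.
#' @return AUC in `[0, 1]`.
#' @export
mortality_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  keep <- labels != "excluded_censored" & !is.na(scores)
  y <- labels[keep] == "died_within"
  s <- scores[keep]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("need at least one death and one survivor")
  r <- rank(s) # midranks
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: for each case, the fraction of controls it
# beats (ties half); for each control, the fraction of cases it is beaten by.
.delong_components <- function(cases, controls) {
  m <- length(cases); n <- length(controls)
  r_all <- rank(c(cases, controls))
  r_cases <- rank(cases)
  r_controls <- rank(controls)
  v10 <- (r_all[seq_len(m)] - r_cases) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_controls) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's test for two correlated AUCs
#'
#' Nonparametric comparison of the mortality AUCs of two clocks scored on
#' the identical label set, using DeLong's structural-components estimate
#' of the covariance of the paired AUCs and a two-sided normal test on the
#' AUC difference.
#'
#' @param scores_1,scores_2 Paired per-subject scores.
#' @param labels A [mortality_labels()] vector.
#' @param names Clock names for display.
#' @return A list of class `"roc_comparison"`: `auc_1`, `auc_2`,
#'   `auc_diff`, `var_diff`, `cov` (2x2 covariance of the AUC pair), `z`,
#'   `p`, `degenerate` (TRUE when the variance of the difference is zero,
#'   in which case `p = 1`).
#' @export
delong_test <- function(scores_1, scores_2, labels,
                        names = c("clock1", "clock2")) {
  stopifnot(length(scores_1) == length(labels),
            length(scores_2) == length(labels))
  keep <- labels != "excluded_censored" & !is.na(scores_1) & !is.na(scores_2)
  y <- labels[keep] == "died_within"
  s1 <- scores_1[keep]; s2 <- scores_2[keep]
  m <- sum(y); n <- sum(!y)
  if (m == 0L || n == 0L) stop("need at least one death and one survivor")
  c1 <- .delong_components(s1[y], s1[!y])
  c2 <- .delong_components(s2[y], s2[!y])
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  degenerate <- !is.finite(var_diff) || var_diff <= .Machine$double.eps
  z <- if (degenerate) 0 else (c1$auc - c2$auc) / sqrt(var_diff)
  p <- if (degenerate) 1 else 2 * stats::pnorm(-abs(z))
  structure(list(names = names, auc_1 = c1$auc, auc_2 = c2$auc,
                 auc_diff = c1$auc - c2$auc, var_diff = var_diff,
                 cov = S, z = z, p = p, degenerate = degenerate,
                 n_cases = m, n_controls = n),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("DeLong comparison: %s (AUC = %.4f) vs %s (AUC = %.4f)\n",
              x$names[1], x$auc_1, x$names[2], x$auc_2))
  cat(sprintf("  dAUC = %+.4f, z = %.3f, p = %.3g%s\n", x$auc_diff, x$z, x$p,
              if (x$degenerate) "  [degenerate variance]" else ""))
  invisible(x)
}

#' Attach theoretical reference clocks
#'
#' Adds `score_ChronAge` (chronological age itself), `score_RandomAge`
#' (chronological age plus Gaussian noise, default SD 10 years — a
#' degraded-information reference), and, for synthetic cohorts with ground
#' truth, `score_CrystalAge` (the perfect forecast,
#' [attach_true_death_forecast()]).
#'
#' @param cohort A cohort `data.frame`.
#' @param noise_sd RandomAge noise SD in years.
#' @param seed Seed for the RandomAge noise.
#' @param crystal `"auto"` attaches CrystalAge when ground truth is
#'   present; `TRUE` requires it (error on real data); `FALSE` omits it.
#' @return The cohort with reference score columns added.
#' @export
reference_clocks <- function(cohort, noise_sd = 10, seed = 1L,
                             crystal = "auto") {
  validate_cohort(cohort)
  cohort$score_ChronAge <- cohort$chron_age
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  cohort$score_RandomAge <- cohort$chron_age +
    stats::rnorm(nrow(cohort), sd = noise_sd)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  has_truth <- "true_death_time" %in% names(cohort)
  if (isTRUE(crystal) && !has_truth) {
    stop("CrystalAge requires ground-truth death times; ",
         "it is only defined for synthetic cohorts")
  }
  if ((isTRUE(crystal) || identical(crystal, "auto")) && has_truth) {
    cohort <- attach_true_death_forecast(cohort)
  }
  cohort
}

#' Kaplan-Meier quartile stratification within age bins
#'
#' Within each chronological-age bin, subjects are ranked by each clock's
#' score; the lowest (biologically youngest, best) and highest (worst) 25%
#' quartiles are selected (boundary ties broken by subject-id order).
#' Kaplan-Meier curves with Greenwood 95% bands are computed per
#' (bin, clock, quartile) cell, and within each (bin, quartile) the clocks
#' are compared pairwise by log-rank tests with Benjamini-Hochberg
#' adjustment over the bin's family of comparisons. Quartile membership of
#' different clocks overlaps; the log-rank test compares the two selected
#' subject groups as sampled.
#'
#' @param cohort A cohort `data.frame`.
#' @param score_cols Names of score columns to compare (higher = older).
#' @param age_breaks Left-closed bin breaks in years (default 10-year bins
#'   35-85).
#' @param horizon Truncate follow-up at this many years.
#' @param min_cell Minimum subjects per (bin, quartile) cell; undersized
#'   cells are skipped with a warning.
#' @return A list of class `"stratified_km"`: `km` (a data.frame of KM
#'   step-function points: bin, clock, quartile, time, surv, lower,
#'   upper, n_risk) and `tests` (bin, quartile, clock_1, clock_2, chisq,
#'   p, p_adj).
#' @export
stratified_km <- function(cohort, score_cols,
                          age_breaks = seq(35, 85, by = 10),
                          horizon = NULL, min_cell = 20L) {
  validate_cohort(cohort)
  miss <- setdiff(score_cols, names(cohort))
  if (length(miss) > 0L) stop("missing score column(s): ",
                              paste(miss, collapse = ", "))
  time <- cohort$follow_up_time
  status <- cohort$event == "died"
  if (!is.null(horizon)) {
    status <- status & time <= horizon
    time <- pmin(time, horizon)
  }
  bins <- cut(cohort$chron_age, breaks = age_breaks, right = FALSE,
              include.lowest = FALSE)
  km_rows <- list()
  test_rows <- list()
  for (b in levels(bins)) {
    in_bin <- which(!is.na(bins) & bins == b)
    if (length(in_bin) == 0L) next
    members <- list()
    for (cl in score_cols) {
      sc <- cohort[[cl]][in_bin]
      ok <- in_bin[!is.na(sc)]
      sc <- sc[!is.na(cohort[[cl]][in_bin])]
      ord <- ok[order(sc, cohort$id[ok])] # stable tie-break on id
      q <- floor(length(ord) / 4)
      if (q < min_cell) {
        warning("skipping bin ", b, " for clock ", cl,
                ": quartile cell size ", q, " < ", min_cell)
        next
      }
      members[[cl]] <- list(`lowest 25%` = ord[seq_len(q)],
                            `highest 25%` = ord[seq(length(ord) - q + 1,
                                                    length(ord))])
    }
    for (cl in names(members)) {
      for (qt in names(members[[cl]])) {
        idx <- members[[cl]][[qt]]
        sf <- survival::survfit(survival::Surv(time[idx], status[idx]) ~ 1,
                                conf.type = "log-log")
        km_rows[[length(km_rows) + 1L]] <- data.frame(
          bin = b, clock = cl, quartile = qt,
          time = sf$time, surv = sf$surv, lower = sf$lower,
          upper = sf$upper, n_risk = sf$n.risk, stringsAsFactors = FALSE)
      }
    }
    cls <- names(members)
    if (length(cls) >= 2L) {
      for (qt in c("lowest 25%", "highest 25%")) {
        for (i in seq_len(length(cls) - 1L)) {
          for (j in seq((i + 1L), length(cls))) {
            g1 <- members[[cls[i]]][[qt]]
            g2 <- members[[cls[j]]][[qt]]
            idx <- c(g1, g2)
            grp <- rep(c(1L, 2L), c(length(g1), length(g2)))
            if (identical(sort(g1), sort(g2))) {
              chisq <- 0; p <- 1
            } else {
              sd_ <- survival::survdiff(
                survival::Surv(time[idx], status[idx]) ~ grp)
              chisq <- sd_$chisq
              p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
            }
            test_rows[[length(test_rows) + 1L]] <- data.frame(
              bin = b, quartile = qt, clock_1 = cls[i], clock_2 = cls[j],
              chisq = chisq, p = p, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  tests <- if (length(test_rows)) do.call(rbind, test_rows) else
    data.frame(bin = character(), quartile = character(),
               clock_1 = character(), clock_2 = character(),
               chisq = numeric(), p = numeric())
  # BH family: all comparisons within one age bin (one figure panel)
  tests$p_adj <- rep(NA_real_, nrow(tests))
  for (b in unique(tests$bin)) {
    fam <- tests$bin == b
    tests$p_adj[fam] <- stats::p.adjust(tests$p[fam], method = "BH")
  }
  structure(list(km = if (length(km_rows)) do.call(rbind, km_rows) else NULL,
                 tests = tests, age_breaks = age_breaks, horizon = horizon),
            class = "stratified_km")
}

#' @export
print.stratified_km <- function(x, ...) {
  cat("Stratified Kaplan-Meier comparison\n")
  if (!is.null(x$km)) {
    cells <- unique(x$km[c("bin", "clock", "quartile")])
    cat(" ", nrow(cells), "KM cells;", nrow(x$tests),
        "pairwise log-rank tests (BH-adjusted per age bin)\n")
  }
  if (nrow(x$tests) > 0L) print(utils::head(x$tests, 10), row.names = FALSE)
  invisible(x)
}

#' Correlation of a clock with chronological age
#'
#' Pearson correlation plus the OLS line of biological age on
#' chronological age. A useful clock is strongly CA-correlated (CA is a
#' first-order approximation of biological age) while departing from the
#' identity line for individual subjects.
#'
#' @param ba Clock ages (years).
#' @param ca Chronological ages (years).
#' @return A list with `r`, `slope`, `intercept`, `n`.
#' @export
correlate_with_ca <- function(ba, ca) {
  keep <- !is.na(ba) & !is.na(ca)
  ba <- ba[keep]; ca <- ca[keep]
  if (length(ba) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(ca) == 0) stop("chronological age has zero variance")
  cf <- stats::coef(stats::lm(ba ~ ca))
  list(r = stats::cor(ba, ca), slope = unname(cf[2]),
       intercept = unname(cf[1]), n = length(ba))
}
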