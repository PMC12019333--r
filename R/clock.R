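#' Fit the chronological-age-only null model (Gompertz slope)
#'
#' Fits a Cox proportional-hazards model with chronological age as the sole
#' covariate. Under a Gompertz mortality law the age coefficient estimates
#' the Gompertz slope \eqn{\gamma}, and the mortality-rate doubling time is
#' \eqn{\mathrm{MRDT} = \ln 2 / \gamma} (about 8 years in human
#' populations). The null model anchors the mapping from log-hazard to
#' years of biological age.
#'
#' @param cohort A cohort `data.frame` with survival follow-up.
#' @param min_events Minimum number of deaths required.
#' @return A list with `gamma`, `gamma_se`, `mrdt`, `mrdt_se` (delta
#'   method), `n`, `events` and the underlying `coxph` fit.
#' @export
fit_null_model <- function(cohort, min_events = 20L) {
  validate_cohort(cohort)
  d <- data.frame(time = cohort$follow_up_time,
                  status = cohort$event == "died",
                  chron_age = cohort$chron_age)
  if (sum(d$status) < min_events) {
    stop("too few events for the null model (", sum(d$status), " < ",
         min_events, ")")
  }
  fit <- survival::coxph(survival::Surv(time, status) ~ chron_age, data = d,
                         ties = "efron")
  gamma <- unname(stats::coef(fit)[["chron_age"]])
  se <- unname(sqrt(stats::vcov(fit)[1, 1]))
  if (!is.finite(gamma) || gamma <= 0) {
    stop("null-model age coefficient is not positive; ",
         "mortality must increase with age for a Gompertz age mapping")
  }
  list(gamma = gamma, gamma_se = se, mrdt = log(2) / gamma,
       mrdt_se = log(2) * se / gamma^2,
       n = nrow(d), events = sum(d$status), fit = fit)
}

.fit_centering <- function(eta, chron_age, type) {
  if (type == "global") {
    c(a = mean(eta), b = 0)
  } else {
    cf <- stats::coef(stats::lm(eta ~ chron_age))
    c(a = unname(cf[1]), b = unname(cf[2]))
  }
}

#' Train a principal-component biological-age clock
#'
#' One call runs the full training pipeline on a cohort table: study
#' exclusions, per-sex robust reference normalization ([fit_reference()],
#' [normalize_cohort()]), sex-specific SVD ([fit_factor_model()]),
#' component selection ([select_components()]), a per-sex Cox
#' proportional-hazards fit on the selected PC scores, the
#' chronological-age-only null model ([fit_null_model()]) for the Gompertz
#' slope, and per-sex centering of the linear predictor on chronological
#' age.
#'
#' A subject's biological age is
#' \deqn{\mathrm{BA} = \mathrm{CA} + \{\eta - \hat\eta(\mathrm{CA})\}/\gamma,}
#' where \eqn{\eta = \sum_k \beta_k p_k} is the Cox linear predictor over
#' selected PC scores, \eqn{\hat\eta(\mathrm{CA}) = a + b\,\mathrm{CA}} the
#' training-cohort centering line, and \eqn{\gamma} the Gompertz slope.
#' Raising \eqn{\eta} by \eqn{\ln 2} (one hazard doubling) raises BA by
#' exactly one mortality-rate doubling time. Chronological age is not a
#' covariate of the PC model (set `include_ca = TRUE` only for ablation
#' studies).
#'
#' @param cohort Training cohort `data.frame`.
#' @param spec A [parameter_spec()]; defaults to the cohort's attached
#'   spec, else identity transforms for all parameter columns.
#' @param exclusions Apply [apply_exclusions()] first.
#' @param age_window,min_reference,mad_constant Passed to [fit_reference()].
#' @param cap,max_missing Passed to [normalize_cohort()].
#' @param policy,fdr,k,r_min Passed to [select_components()].
#' @param centering `"age_conditional"` (OLS of eta on CA, default; makes
#'   the mean age delta zero at every age) or `"global"` (age-independent
#'   mean-eta centering).
#' @param include_ca Add chronological age as a Cox covariate (ablation
#'   only).
#' @param min_events Minimum deaths per sex stratum.
#' @return An object of class `"pcclock"` holding the parameter manifest,
#'   reference stats, factor model, per-sex Cox weights (with SEs),
#'   Gompertz slope `gamma` and `mrdt`, per-sex centering coefficients, and
#'   training provenance. Use [predict.pcclock()] to score subjects,
#'   [write_bundle()] to serialize.
#' @export
pcclock <- function(cohort, spec = NULL, exclusions = TRUE,
                    age_window = c(40, 50), min_reference = 50,
                    mad_constant = 1.4826, cap = 6, max_missing = 0.2,
                    policy = "mortality_fdr", fdr = 0.05, k = 10, r_min = 0.3,
                    centering = c("age_conditional", "global"),
                    include_ca = FALSE, min_events = 20L) {
  centering <- match.arg(centering)
  validate_cohort(cohort)
  if (is.null(spec)) spec <- attr(cohort, "param_spec")
  if (is.null(spec)) spec <- parameter_spec(cohort_params(cohort))
  if (exclusions) cohort <- apply_exclusions(cohort, quiet = TRUE)

  ref <- fit_reference(cohort, spec, age_window = age_window,
                       min_reference = min_reference,
                       mad_constant = mad_constant)
  design <- normalize_cohort(cohort, ref, cap = cap, max_missing = max_missing)
  cohort <- cohort[match(rownames(design), cohort$id), , drop = FALSE]

  fm <- fit_factor_model(design)
  scores <- project_scores(design, fm)
  fm <- select_components(fm, scores, cohort, policy = policy, fdr = fdr,
                          k = k, r_min = r_min)

  weights <- list()
  cox_fits <- list()
  for (s in names(fm$by_sex)) {
    comps <- intersect(fm$by_sex[[s]]$components, fm$selected)
    rows <- scores$sex == s
    if (length(comps) == 0L) {
      stop("no selected components for sex '", s, "'")
    }
    dat <- scores[rows, comps, drop = FALSE]
    if (include_ca) dat$chron_age <- cohort$chron_age[rows]
    dat <- as.data.frame(dat, check.names = FALSE)
    if (sum(cohort$event[rows] == "died") < min_events) {
      stop("too few events in sex stratum '", s, "'")
    }
    qrX <- qr(as.matrix(dat))
    if (qrX$rank < ncol(dat)) {
      dep <- colnames(dat)[-seq_len(qrX$rank)]
      stop("collinear covariates in sex '", s, "': ",
           paste(dep, collapse = ", "))
    }
    surv <- survival::Surv(cohort$follow_up_time[rows],
                           cohort$event[rows] == "died")
    fit <- survival::coxph(surv ~ ., data = dat, ties = "efron")
    if (!is.null(fit$fail) || any(!is.finite(stats::coef(fit)))) {
      stop("Cox model failed to converge for sex '", s, "'")
    }
    sm <- summary(fit)$coefficients
    weights[[s]] <- data.frame(component = rownames(sm),
                               beta = sm[, "coef"],
                               se = sm[, "se(coef)"],
                               z = sm[, "z"], p = sm[, "Pr(>|z|)"],
                               row.names = NULL, stringsAsFactors = FALSE)
    cox_fits[[s]] <- fit
  }

  null <- fit_null_model(cohort, min_events = min_events)

  cent <- list()
  eta_train <- rep(NA_real_, nrow(scores))
  for (s in names(weights)) {
    rows <- scores$sex == s
    w <- weights[[s]]
    pc_w <- w[w$component != "chron_age", , drop = FALSE]
    eta <- as.matrix(scores[rows, pc_w$component, drop = FALSE]) %*% pc_w$beta
    if (include_ca) {
      eta <- eta + cohort$chron_age[rows] *
        w$beta[w$component == "chron_age"]
    }
    eta_train[rows] <- drop(eta)
    cent[[s]] <- .fit_centering(drop(eta), cohort$chron_age[rows], centering)
  }

  obj <- list(
    spec = attr(ref, "spec"), reference = ref, factor_model = fm,
    weights = weights, gamma = null$gamma, gamma_se = null$gamma_se,
    mrdt = null$mrdt, centering = cent, centering_type = centering,
    include_ca = include_ca, cap = cap, max_missing = max_missing,
    score_scale = "raw",
    training = list(
      n = nrow(cohort), events = null$events,
      n_by_sex = table(cohort$sex),
      eta = stats::setNames(eta_train, scores$id),
      sex = stats::setNames(scores$sex, scores$id),
      chron_age = stats::setNames(cohort$chron_age, cohort$id),
      selection_table = attr(fm, "selection_table"),
      version = as.character(utils::packageVersion("pcclock"))),
    null_fit = null$fit, cox_fits = cox_fits
  )
  class(obj) <- "pcclock"
  obj
}

#' Score subjects with a trained clock
#'
#' Normalizes the new subjects against the clock's stored reference
#' statistics, projects them onto the stored loadings, applies the Cox
#' weights, and maps the linear predictor to a biological age in years via
#' the Gompertz slope. Per-PC contributions (in years) decompose the age
#' delta exactly: \eqn{\sum_k \beta_k p_k/\gamma - \hat\eta(CA)/\gamma =
#' BA - CA}.
#'
#' Scored biological ages are not clamped; deltas beyond +35 years or BAs
#' above 105 years (outside the range seen in validation cohorts) trigger a
#' warning, never truncation.
#'
#' @param object A `"pcclock"` object.
#' @param newdata A cohort `data.frame` to score.
#' @param ... Unused.
#' @return A `data.frame` of class `"ba_result"` with columns `id`, `sex`,
#'   `chron_age`, `eta`, `biological_age`, `delta`, `centering_term`
#'   (years), and the per-PC year contributions as attribute
#'   `"contributions"` (subjects x selected components; other-sex
#'   components `NA`).
#' @export
predict.pcclock <- function(object, newdata, ...) {
  validate_cohort(newdata)
  bad_sex <- setdiff(unique(newdata$sex), names(object$weights))
  if (length(bad_sex) > 0L) {
    stop("clock has no weights for sex: ", paste(bad_sex, collapse = ", "))
  }
  design <- normalize_cohort(newdata, object$reference, cap = object$cap,
                             max_missing = object$max_missing)
  newdata <- newdata[match(rownames(design), newdata$id), , drop = FALSE]
  scores <- project_scores(design, object$factor_model, selected_only = TRUE)

  n <- nrow(scores)
  comps <- object$factor_model$selected
  contrib <- matrix(NA_real_, n, length(comps),
                    dimnames = list(scores$id, comps))
  eta <- rep(NA_real_, n)
  cent_term <- rep(NA_real_, n)
  gamma <- object$gamma
  for (s in names(object$weights)) {
    rows <- scores$sex == s
    if (!any(rows)) next
    w <- object$weights[[s]]
    pc_w <- w[w$component != "chron_age", , drop = FALSE]
    p <- as.matrix(scores[rows, pc_w$component, drop = FALSE])
    bp <- sweep(p, 2L, pc_w$beta, `*`)
    contrib[rows, pc_w$component] <- bp / gamma
    e <- rowSums(bp)
    if (object$include_ca) {
      e <- e + newdata$chron_age[rows] * w$beta[w$component == "chron_age"]
    }
    eta[rows] <- e
    ab <- object$centering[[s]]
    cent_term[rows] <- (ab[["a"]] + ab[["b"]] * newdata$chron_age[rows]) / gamma
  }
  ca <- newdata$chron_age
  delta <- eta / gamma - cent_term
  ba <- ca + delta
  if (any(delta > 35 | ba > 105, na.rm = TRUE)) {
    warning("scored deltas above +35 years or biological ages above 105 ",
            "years; values are reported unclamped")
  }
  out <- data.frame(id = scores$id, sex = scores$sex, chron_age = ca,
                    eta = eta, biological_age = ba, delta = delta,
                    centering_term = cent_term, stringsAsFactors = FALSE)
  attr(out, "contributions") <- contrib
  class(out) <- c("ba_result", "data.frame")
  out
}

#' @export
print.pcclock <- function(x, ...) {
  cat("Principal-component biological-age clock\n")
  cat(sprintf("  parameters: %d retained (%d log-transformed)\n",
              nrow(x$spec), sum(x$spec$transform == "log")))
  for (s in names(x$weights)) {
    cat(sprintf("  %s: %d selected PCs of %d (n = %d)\n", s,
                nrow(x$weights[[s]]) - as.integer(x$include_ca),
                length(x$factor_model$by_sex[[s]]$components),
                x$factor_model$by_sex[[s]]$n))
  }
  cat(sprintf("  Gompertz slope gamma = %.4f /y  (MRDT = %.2f y)\n",
              x$gamma, x$mrdt))
  cat(sprintf("  centering: %s\n", x$centering_type))
  invisible(x)
}

#' @export
summary.pcclock <- function(object, ...) {
  structure(list(clock = object), class = "summary.pcclock")
}

#' @export
print.summary.pcclock <- function(x, ...) {
  cl <- x$clock
  print(cl)
  cat(sprintf("\nTraining: n = %d subjects, %d deaths\n",
              cl$training$n, cl$training$events))
  cat(sprintf("MRDT = %.2f y (gamma = %.4f +/- %.4f /y)\n\n",
              cl$mrdt, cl$gamma, cl$gamma_se))
  for (s in names(cl$weights)) {
    cat("Cox weights (", s, "):\n", sep = "")
    print(cl$weights[[s]], digits = 3, row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' @export
coef.pcclock <- function(object, ...) {
  unlist(lapply(object$weights, function(w)
    stats::setNames(w$beta, w$component)), use.names = TRUE)
}

#' Training-set age deltas as residuals
#'
#' The clock's residual for a training subject is its age delta
#' (biological minus chronological age): the part of log-mortality risk,
#' in years, not explained by chronological age.
#' @param object A `"pcclock"` object.
#' @param ... Unused.
#' @export
residuals.pcclock <- function(object, ...) {
  eta <- object$training$eta
  sex <- object$training$sex[names(eta)]
  ca <- object$training$chron_age[names(eta)]
  delta <- rep(NA_real_, length(eta))
  for (s in names(object$centering)) {
    ab <- object$centering[[s]]
    rows <- sex == s
    delta[rows] <- (eta[rows] - (ab[["a"]] + ab[["b"]] * ca[rows])) /
      object$gamma
  }
  stats::setNames(delta, names(eta))
}

#' Plot a trained clock
#'
#' `which = "scree"` draws the per-sex singular-value spectrum;
#' `which = "centering"` draws the training linear predictor against
#' chronological age with the per-sex centering lines.
#'
#' @param x A `"pcclock"` object.
#' @param which `"scree"` or `"centering"`.
#' @param ... Passed to the underlying plot call.
#' @export
plot.pcclock <- function(x, which = c("scree", "centering"), ...) {
  which <- match.arg(which)
  if (which == "scree") {
    sexes <- names(x$factor_model$by_sex)
    d1 <- x$factor_model$by_sex[[sexes[1]]]$d
    graphics::plot(seq_along(d1), d1, type = "b", pch = 16,
                   xlab = "component", ylab = "singular value",
                   main = "Singular-value spectrum", ...)
    if (length(sexes) > 1L) {
      d2 <- x$factor_model$by_sex[[sexes[2]]]$d
      graphics::lines(seq_along(d2), d2, type = "b", pch = 1, lty = 2)
      graphics::legend("topright", legend = sexes, pch = c(16, 1),
                       lty = c(1, 2), bty = "n")
    }
  } else {
    eta <- x$training$eta
    ca <- x$training$chron_age[names(eta)]
    graphics::plot(ca, eta, pch = ".", xlab = "chronological age (y)",
                   ylab = "Cox linear predictor", main = "Centering", ...)
    for (s in names(x$centering)) {
      graphics::abline(x$centering[[s]][["a"]], x$centering[[s]][["b"]],
                       lty = if (s == "male") 1 else 2)
    }
  }
  invisible(x)
}
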