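#' Clinical parameter manifest
#'
#' A parameter spec names each clinical parameter used by the clock, the
#' per-parameter transform applied before normalization (`"identity"` or
#' `"log"`; log only for strictly positive-valued parameters), its units,
#' and whether it is required. The pipeline accepts any spec list; real
#' deployments ship a curated manifest (the published clock uses 60
#' parameters).
#'
#' @param name Character vector of unique parameter names.
#' @param transform `"identity"` or `"log"`, recycled.
#' @param units Units string, recycled.
#' @param required Logical, recycled.
#' @return A `data.frame` of class `"parameter_spec"`.
#' @export
parameter_spec <- function(name, transform = "identity", units = "",
                           required = FALSE) {
  if (anyDuplicated(name)) stop("parameter names must be unique")
  transform <- rep_len(transform, length(name))
  if (!all(transform %in% c("identity", "log"))) {
    stop("transform must be 'identity' or 'log'")
  }
  out <- data.frame(name = as.character(name), transform = transform,
                    units = rep_len(units, length(name)),
                    required = rep_len(required, length(name)),
                    stringsAsFactors = FALSE)
  class(out) <- c("parameter_spec", "data.frame")
  out
}

.apply_transform <- function(x, transform) {
  if (transform == "log") {
    bad <- !is.na(x) & x <= 0
    if (any(bad)) stop("log transform requires strictly positive values")
    log(x)
  } else {
    x
  }
}

#' Apply the study exclusions
#'
#' Removes (a) subjects whose chronological age is top-coded in the source
#' survey (the exact age is unknowable, so age-dependent modelling is
#' impossible for them) and (b) subjects who died of accidental causes,
#' which are deemed not age-related. Counts removed under each rule are
#' attached as attribute `"exclusions"` and reported via a message.
#'
#' @param cohort A cohort `data.frame` with `age_top_coded` and
#'   `cause_of_death` columns.
#' @param accidental_category Label used for accidental deaths.
#' @param quiet Suppress the message.
#' @return The filtered cohort with attribute `"exclusions"` =
#'   `c(age_top_coded = , accidental = )`.
#' @export
apply_exclusions <- function(cohort, accidental_category = "accidental",
                             quiet = FALSE) {
  validate_cohort(cohort)
  top <- if ("age_top_coded" %in% names(cohort))
    cohort$age_top_coded %in% TRUE else rep(FALSE, nrow(cohort))
  acc <- if ("cause_of_death" %in% names(cohort))
    cohort$event == "died" & cohort$cause_of_death %in% accidental_category
  else rep(FALSE, nrow(cohort))
  out <- cohort[!(top | acc), , drop = FALSE]
  counts <- c(age_top_coded = sum(top), accidental = sum(acc & !top))
  attr(out, "exclusions") <- counts
  if (!quiet) {
    message("excluded ", counts[["age_top_coded"]], " age-top-coded and ",
            counts[["accidental"]], " accidental-death subjects (",
            nrow(out), " remain)")
  }
  if (nrow(out) == 0L) warning("all subjects excluded")
  out
}

#' Fit per-sex robust reference statistics
#'
#' Computes, separately for males and females, the median and raw median
#' absolute deviation (MAD, unscaled) of each transformed parameter over a
#' young, generally healthy reference stratum (default ages \[40, 50)
#' years). These statistics anchor the robust z-score normalization: using
#' a fixed young-adult reference makes z-scores comparable across survey
#' waves and mitigates batch effects. Parameters with zero reference MAD in
#' either sex carry no usable spread and are dropped with a warning.
#'
#' @param cohort A cohort `data.frame`.
#' @param spec A [parameter_spec()]; defaults to the cohort's attached spec.
#' @param age_window Reference age window `[lo, hi)` in years.
#' @param min_reference Minimum reference subjects per sex.
#' @param mad_constant Consistency constant by which the raw MAD is scaled
#'   at normalization time (1.4826 makes the MAD estimate the SD under
#'   Gaussian data, so the six-SD cap is commensurable).
#' @param reference_subset Optional logical/index vector selecting an
#'   explicit reference subset instead of the age window (a hook for
#'   callers with a health-screened reference).
#' @return An object of class `"reference_stats"`: a `data.frame` with
#'   columns `sex`, `parameter`, `median`, `mad`, `n`, plus attributes
#'   `mad_constant`, `age_window`, `dropped` (zero-MAD parameters) and
#'   `params` (retained parameter names, in spec order).
#' @export
fit_reference <- function(cohort, spec = attr(cohort, "param_spec"),
                          age_window = c(40, 50), min_reference = 50,
                          mad_constant = 1.4826, reference_subset = NULL) {
  validate_cohort(cohort)
  if (is.null(spec)) {
    spec <- parameter_spec(cohort_params(cohort))
  }
  miss <- setdiff(spec$name, names(cohort))
  if (length(miss) > 0L) {
    stop("cohort lacks parameter column(s): ", paste(miss, collapse = ", "))
  }
  ref <- if (!is.null(reference_subset)) cohort[reference_subset, , drop = FALSE]
  else cohort[cohort$chron_age >= age_window[1] &
                cohort$chron_age < age_window[2], , drop = FALSE]
  rows <- list()
  for (s in c("male", "female")) {
    sub <- ref[ref$sex == s, , drop = FALSE]
    if (nrow(sub) < min_reference) {
      stop("too few reference subjects for sex stratum '", s, "' (",
           nrow(sub), " < ", min_reference, ")")
    }
    for (i in seq_len(nrow(spec))) {
      x <- .apply_transform(sub[[spec$name[i]]], spec$transform[i])
      x <- x[!is.na(x)]
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, parameter = spec$name[i],
        median = stats::median(x),
        mad = stats::mad(x, constant = 1),
        n = length(x), stringsAsFactors = FALSE)
    }
  }
  stats_df <- do.call(rbind, rows)
  zero <- unique(stats_df$parameter[!is.finite(stats_df$mad) |
                                      stats_df$mad <= 0])
  if (length(zero) > 0L) {
    warning("dropping parameter(s) with zero reference MAD: ",
            paste(zero, collapse = ", "))
    stats_df <- stats_df[!stats_df$parameter %in% zero, , drop = FALSE]
  }
  retained <- setdiff(spec$name, zero)
  if (length(retained) == 0L) stop("no parameter has positive reference MAD")
  structure(stats_df,
            mad_constant = mad_constant, age_window = age_window,
            dropped = zero, params = retained,
            spec = spec[spec$name %in% retained, , drop = FALSE],
            class = c("reference_stats", "data.frame"))
}

#' Build the normalized design matrix
#'
#' Transforms each retained parameter (identity or log), centers by the
#' sex-specific reference median, scales by `mad_constant * MAD`, imputes
#' missing values at z = 0 (the reference median), and caps the result at
#' \eqn{\pm}`cap` robust SDs. Subjects missing more than `max_missing` of
#' the retained parameters are dropped (too little information to impute).
#'
#' @param cohort A cohort `data.frame`.
#' @param stats A [fit_reference()] result.
#' @param cap Cap in robust SD units (default 6).
#' @param max_missing Per-subject missingness fraction above which the
#'   subject is dropped.
#' @return A numeric matrix (subjects x parameters) of class
#'   `"design_matrix"` with `rownames` = subject ids and attributes `sex`
#'   (per-row label), `params`, `cap` and `dropped_subjects`.
#' @export
normalize_cohort <- function(cohort, stats, cap = 6, max_missing = 0.2) {
  validate_cohort(cohort)
  stopifnot(inherits(stats, "reference_stats"))
  spec <- attr(stats, "spec")
  params <- attr(stats, "params")
  mc <- attr(stats, "mad_constant")
  miss <- setdiff(params, names(cohort))
  if (length(miss) > 0L) {
    stop("cohort lacks parameter column(s): ", paste(miss, collapse = ", "))
  }
  bad_sex <- setdiff(unique(cohort$sex), unique(stats$sex))
  if (length(bad_sex) > 0L) {
    stop("no reference stats for sex: ", paste(bad_sex, collapse = ", "))
  }
  Z <- matrix(NA_real_, nrow(cohort), length(params),
              dimnames = list(cohort$id, params))
  for (s in unique(cohort$sex)) {
    rows <- cohort$sex == s
    st <- stats[stats$sex == s, , drop = FALSE]
    med <- st$median[match(params, st$parameter)]
    mad_ <- st$mad[match(params, st$parameter)]
    for (j in seq_along(params)) {
      x <- .apply_transform(cohort[[params[j]]][rows],
                            spec$transform[match(params[j], spec$name)])
      Z[rows, j] <- (x - med[j]) / (mc * mad_[j])
    }
  }
  n_miss <- rowSums(is.na(Z))
  drop_subj <- n_miss / length(params) > max_missing
  dropped <- rownames(Z)[drop_subj]
  if (any(drop_subj)) {
    warning("dropping ", sum(drop_subj), " subject(s) with > ",
            round(100 * max_missing), "% missing parameters")
  }
  Z <- Z[!drop_subj, , drop = FALSE]
  Z[is.na(Z)] <- 0
  Z[Z > cap] <- cap
  Z[Z < -cap] <- -cap
  structure(Z, sex = cohort$sex[!drop_subj], params = params, cap = cap,
            dropped_subjects = dropped, class = c("design_matrix", "matrix"))
}
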