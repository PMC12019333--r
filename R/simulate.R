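#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration for [simulate_cohort()]. The generator
#' emulates the structure of a population survey cohort with linked
#' mortality follow-up: sex-stratified continuous clinical parameters driven
#' by a small number of correlated latent physiological factors, linear age
#' trends, Gompertz all-cause mortality with administrative right-censoring,
#' cause-of-death categories, and healthspan questionnaire/exam fields
#' (processing-speed score, timed walk, instrumental/basic activities of
#' daily living, ability to work).
#'
#' The subject-level hazard is
#' \deqn{h(t) = \lambda_0 \exp\{\gamma (a_0 + t)\} \exp(r),}
#' where \eqn{a_0} is age at entry, \eqn{\gamma} the Gompertz slope
#' (mortality-rate doubling time \eqn{\mathrm{MRDT} = \ln 2 / \gamma}), and
#' \eqn{r = \sum_k \beta_k z_k} the latent log-hazard burden.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Entry ages are uniform on `[min, max]` years.
#' @param sex_ratio Fraction of male subjects.
#' @param n_latent Number of latent physiological factors.
#' @param n_params Number of observed clinical parameters (default 60).
#' @param loading_seed_matrix Optional `n_params x n_latent` matrix of
#'   latent-to-parameter effect sizes (standardized units). By default a
#'   block structure is drawn once from the seed: each parameter loads
#'   mainly on one latent (|loading| in \[0.5, 1\]) with small
#'   cross-loadings.
#' @param latent_scales Per-latent strength multipliers applied to the
#'   block loadings; the decreasing default gives the latent factors
#'   distinct explained variances (as in real clinical data, where the
#'   leading component dominates), which keeps the factor structure
#'   identifiable. Recycled/truncated to `n_latent`.
#' @param noise_sd Residual SD of each parameter on the standardized scale.
#' @param age_slope_range Each parameter receives a linear age slope drawn
#'   once, uniform on this range (standardized units per year), so that
#'   parameters — and hence principal components — correlate with
#'   chronological age.
#' @param gamma_true Gompertz slope (1/years); default `log(2)/8`, i.e. an
#'   8-year mortality-rate doubling time.
#' @param baseline_hazard Hazard (events/year) at age 0 for a subject with
#'   zero latent burden.
#' @param latent_effects Per-latent log-hazard coefficients (per SD of the
#'   latent); recycled/truncated to `n_latent`.
#' @param follow_up_years Administrative censoring horizon (years).
#' @param missing_rate Fraction of parameter and healthspan values set
#'   missing completely at random, in `[0, 1)`.
#' @param top_code_age Ages at or above this value are flagged
#'   `age_top_coded` (exact age unknowable in the source survey).
#' @param rng_seed Integer seed; the generator is deterministic given the
#'   full configuration.
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [simulate_cohort()], [attach_true_death_forecast()]
#' @export
sim_config <- function(n_subjects = 1000L,
                       age_range = c(30, 84),
                       sex_ratio = 0.5,
                       n_latent = 3L,
                       n_params = 60L,
                       loading_seed_matrix = NULL,
                       latent_scales = 1.3 * 0.75^(seq_len(n_latent) - 1),
                       noise_sd = 1,
                       age_slope_range = c(0.002, 0.02),
                       gamma_true = log(2) / 8,
                       baseline_hazard = 3e-5,
                       latent_effects = c(0.5, 0.35, 0.2),
                       follow_up_years = 20,
                       missing_rate = 0.02,
                       top_code_age = 85,
                       rng_seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), age_range = as.numeric(age_range),
    sex_ratio = sex_ratio, n_latent = as.integer(n_latent),
    n_params = as.integer(n_params),
    loading_seed_matrix = loading_seed_matrix,
    latent_scales = rep_len(as.numeric(latent_scales), n_latent),
    noise_sd = noise_sd,
    age_slope_range = as.numeric(age_slope_range), gamma_true = gamma_true,
    baseline_hazard = baseline_hazard,
    latent_effects = rep_len(as.numeric(latent_effects), n_latent),
    follow_up_years = follow_up_years, missing_rate = missing_rate,
    top_code_age = top_code_age, rng_seed = as.integer(rng_seed)
  )
  .check_cfg <- function(ok, field, msg) {
    if (!ok) stop("invalid sim_config field '", field, "': ", msg)
  }
  .check_cfg(cfg$n_subjects >= 1L, "n_subjects", "must be >= 1")
  .check_cfg(length(cfg$age_range) == 2L && cfg$age_range[1] < cfg$age_range[2],
             "age_range", "must be an increasing [min, max] pair")
  .check_cfg(cfg$sex_ratio >= 0 && cfg$sex_ratio <= 1, "sex_ratio",
             "must lie in [0, 1]")
  .check_cfg(cfg$n_latent >= 1L, "n_latent", "must be >= 1")
  .check_cfg(cfg$n_params >= cfg$n_latent, "n_params", "must be >= n_latent")
  .check_cfg(cfg$gamma_true > 0, "gamma_true", "must be > 0")
  .check_cfg(cfg$baseline_hazard > 0, "baseline_hazard", "must be > 0")
  .check_cfg(cfg$missing_rate >= 0 && cfg$missing_rate < 1, "missing_rate",
             "must lie in [0, 1)")
  .check_cfg(cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  .check_cfg(cfg$follow_up_years > 0, "follow_up_years", "must be > 0")
  if (!is.null(cfg$loading_seed_matrix)) {
    .check_cfg(is.matrix(cfg$loading_seed_matrix) &&
                 nrow(cfg$loading_seed_matrix) == cfg$n_params &&
                 ncol(cfg$loading_seed_matrix) == cfg$n_latent,
               "loading_seed_matrix", "must be n_params x n_latent")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Exact inverse-transform draw of a Gompertz death time measured from entry:
# H(t) = (lambda/gamma) * exp(gamma*a0) * (exp(gamma*t) - 1), lambda the
# subject's proportional hazard at age 0. Solve H(t) = E, E ~ Exp(1).
.rgompertz <- function(n, a0, gamma, lambda) {
  e <- stats::rexp(n)
  log1p(gamma * e / (lambda * exp(gamma * a0))) / gamma
}

.cod_categories <- c("heart disease", "cancer", "cerebrovascular disease",
                     "chronic lower respiratory disease", "diabetes mellitus",
                     "kidney disease", "accidental", "other")
.cod_probs <- c(0.30, 0.25, 0.08, 0.08, 0.06, 0.04, 0.05, 0.14)

.adl_levels <- c("no difficulty", "some difficulty", "much difficulty",
                 "unable")
.iadl_items <- paste0("adl_i", 1:6)
.badl_items <- paste0("adl_b", 1:7)

# Draw one ADL response per subject from cumulative logits on age + burden.
.draw_adl <- function(age, burden, shift) {
  lp <- 0.05 * (age - 45) + 0.8 * burden - shift
  cut1 <- stats::plogis(lp - 3)   # P(worse than "no difficulty")
  cut2 <- stats::plogis(lp - 5)   # P(worse than "some difficulty")
  cut3 <- stats::plogis(lp - 6.5) # P("unable")
  u <- stats::runif(length(age))
  lev <- 1L + (u < cut1) + (u < cut2) + (u < cut3)
  .adl_levels[lev]
}

#' Simulate a survey-like cohort under a Gompertz mortality law
#'
#' Generates a cohort table with known ground truth so that training,
#' scoring, benchmarking and interpretation are all testable without
#' external downloads. Clinical parameters are latent-factor driven with
#' per-parameter age trends; death times are drawn exactly by inverse
#' transform from the closed-form Gompertz survival function and censored
#' administratively at the follow-up horizon; healthspan fields worsen with
#' latent burden and age. Missingness is completely at random.
#'
#' The uncensored death time is retained in the `true_death_time` column
#' (and true latents in attribute `"latents"`) so that perfect-forecast
#' reference clocks and parameter-recovery checks are possible; both are
#' ground truth that no real cohort would carry.
#'
#' @param config A [sim_config()] object.
#' @return A cohort `data.frame` (see [cohort_params()]) with attributes
#'   `"latents"` (n x k matrix), `"param_spec"` (the matching
#'   [parameter_spec()] table; the first third of parameters are
#'   log-normal and marked for log transform) and `"config"`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, as.list(config))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$rng_seed)

  n <- config$n_subjects
  p <- config$n_params
  k <- config$n_latent

  # structural constants drawn once per configuration
  L <- config$loading_seed_matrix
  if (is.null(L)) {
    block <- rep_len(seq_len(k), p)
    L <- matrix(stats::rnorm(p * k, sd = 0.08), p, k)
    main <- stats::runif(p, 0.5, 1) * sample(c(-1, 1), p, replace = TRUE)
    L[cbind(seq_len(p), block)] <- main
    L <- sweep(L, 2L, config$latent_scales, `*`)
  }
  slopes <- stats::runif(p, config$age_slope_range[1], config$age_slope_range[2]) *
    sample(c(-1, 1), p, replace = TRUE, prob = c(0.3, 0.7))
  n_log <- floor(p / 3)
  transform <- c(rep("log", n_log), rep("identity", p - n_log))
  pnames <- sprintf("par%02d", seq_len(p))
  mu <- stats::runif(p, 1, 100)        # location in native lab units
  sc <- stats::runif(p, 0.5, 20)       # scale in native lab units
  sex_shift <- stats::rnorm(p, sd = 0.4) # standardized male-female offset

  # subjects
  id <- sprintf("S%05d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  z <- matrix(stats::rnorm(n * k), n, k,
              dimnames = list(id, paste0("latent", seq_len(k))))
  burden <- drop(z %*% config$latent_effects)

  # parameters on the standardized scale, then mapped to lab units
  signal <- tcrossprod(z, L) +
    outer(age - 45, slopes) +
    outer(ifelse(sex == "male", 0.5, -0.5), sex_shift) +
    matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
  X <- matrix(0, n, p, dimnames = list(NULL, pnames))
  for (j in seq_len(p)) {
    X[, j] <- if (transform[j] == "log") {
      exp(log(mu[j]) + 0.3 * signal[, j])
    } else {
      mu[j] + sc[j] * signal[, j]
    }
  }

  # mortality
  lambda <- config$baseline_hazard * exp(burden)
  td <- .rgompertz(n, age, config$gamma_true, lambda)
  event <- ifelse(td <= config$follow_up_years, "died", "censored")
  fu <- pmin(td, config$follow_up_years)
  cod <- rep(NA_character_, n)
  died <- event == "died"
  if (any(died)) {
    cod[died] <- sample(.cod_categories, sum(died), replace = TRUE,
                        prob = .cod_probs)
  }

  # healthspan fields
  dsst <- as.integer(round(pmax(0, 55 - 0.25 * (age - 45) - 4 * burden +
                                  stats::rnorm(n, sd = 8))))
  speed <- pmax(0.25, 1.3 - 0.006 * (age - 45) - 0.12 * burden +
                  stats::rnorm(n, sd = 0.15))
  walk_time <- 6.096 / speed
  work_able <- ifelse(
    stats::runif(n) < stats::plogis(-3.5 + 0.06 * (age - 45) + 0.8 * burden),
    "no", "yes")
  adl <- lapply(c(.iadl_items, .badl_items), function(item)
    .draw_adl(age, burden, shift = stats::runif(1, -0.5, 0.5)))
  names(adl) <- c(.iadl_items, .badl_items)

  cohort <- data.frame(
    id = id, sex = sex, chron_age = age,
    follow_up_time = fu, event = event, cause_of_death = cod,
    age_top_coded = age >= config$top_code_age,
    true_death_time = td,
    dsst_score = dsst, walk_time = walk_time, work_able = work_able,
    stringsAsFactors = FALSE
  )
  for (item in names(adl)) cohort[[item]] <- adl[[item]]
  cohort <- cbind(cohort, as.data.frame(X))

  # MCAR missingness on parameters and healthspan fields
  if (config$missing_rate > 0) {
    for (col in c(pnames, "dsst_score", "walk_time", "work_able",
                  names(adl))) {
      drop_i <- stats::runif(n) < config$missing_rate
      cohort[[col]][drop_i] <- NA
    }
  }

  attr(cohort, "latents") <- z
  attr(cohort, "param_spec") <- parameter_spec(
    name = pnames, transform = transform, units = "arbitrary",
    required = FALSE)
  attr(cohort, "config") <- config
  validate_cohort(cohort)
  cohort
}

#' Attach a perfect death-forecast reference clock (CrystalAge)
#'
#' Adds a `score_CrystalAge` column that strictly orders subjects by their
#' true uncensored time to death (earlier death = higher score). CrystalAge
#' is the theoretical ceiling against which real clocks are benchmarked: it
#' attains AUC exactly 1 for any mortality horizon. It is only defined for
#' synthetic cohorts, where the uncensored death time is known.
#'
#' @param cohort A cohort produced by [simulate_cohort()] (must carry the
#'   `true_death_time` column).
#' @return The cohort with a `score_CrystalAge` column added.
#' @export
attach_true_death_forecast <- function(cohort) {
  if (!"true_death_time" %in% names(cohort) ||
      any(!is.finite(cohort$true_death_time))) {
    stop("CrystalAge requires ground-truth death times; ",
         "only synthetic cohorts carry 'true_death_time'")
  }
  cohort$score_CrystalAge <- -cohort$true_death_time
  cohort
}
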