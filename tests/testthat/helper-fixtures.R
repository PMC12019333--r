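# Shared fixtures. Simulated cohorts are cached per test run so several
# test files can reuse the same mid-sized cohort without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

default_cohort <- function(n = 3000, seed = 42, ...) {
  key <- paste0("coh_", n, "_", seed, "_",
                paste(deparse(substitute(list(...))), collapse = ""))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_cohort(
      sim_config(n_subjects = n, rng_seed = seed, ...))
  }
  .fixture_env[[key]]
}

default_clock <- function() {
  if (is.null(.fixture_env$clock)) {
    .fixture_env$clock <- suppressWarnings(pcclock(default_cohort()))
  }
  .fixture_env$clock
}

# A fully hand-specified clock: identity normalization (median 0, raw MAD 1,
# MAD constant 1), a given loading matrix shared by both sexes, given Cox
# weights and centering line. With these choices a subject's z-vector equals
# its raw parameter values, so every downstream number is hand-computable.
make_toy_clock <- function(loadings = diag(2), beta = c(1, 0),
                           gamma = log(2) / 8, a = 0, b = 0) {
  p <- nrow(loadings)
  k <- ncol(loadings)
  params <- sprintf("p%d", seq_len(p))
  rownames(loadings) <- params
  spec <- parameter_spec(params)
  ref <- structure(
    data.frame(sex = rep(c("male", "female"), each = p),
               parameter = rep(params, 2), median = 0, mad = 1, n = 10,
               stringsAsFactors = FALSE),
    mad_constant = 1, age_window = c(40, 50), dropped = character(),
    params = params, spec = spec,
    class = c("reference_stats", "data.frame"))
  by_sex <- list()
  selected <- character()
  for (s in c("male", "female")) {
    comps <- paste0("PC", seq_len(k), c(male = "M", female = "F")[[s]])
    L <- loadings
    colnames(L) <- comps
    by_sex[[s]] <- list(center = stats::setNames(rep(0, p), params),
                        loadings = L, d = rep(1, k), components = comps,
                        n = 10L)
    selected <- c(selected, comps)
  }
  fm <- structure(list(params = params, by_sex = by_sex,
                       selected = selected), class = "factor_model")
  weights <- list()
  for (s in c("male", "female")) {
    weights[[s]] <- data.frame(
      component = by_sex[[s]]$components, beta = rep_len(beta, k),
      se = 0.1, z = 1, p = 0.5, stringsAsFactors = FALSE)
  }
  structure(list(spec = spec, reference = ref, factor_model = fm,
                 weights = weights, gamma = gamma, gamma_se = 1e-3,
                 mrdt = log(2) / gamma,
                 centering = list(male = c(a = a, b = b),
                                  female = c(a = a, b = b)),
                 centering_type = "age_conditional", include_ca = FALSE,
                 cap = 6, max_missing = 0.2, score_scale = "raw",
                 training = list(n = 0L, events = 0L, version = "test")),
            class = "pcclock")
}

# Minimal schema-valid cohort with given parameter values.
toy_cohort <- function(values, age = 60, sex = "male",
                       follow_up = 10, event = "censored") {
  values <- as.matrix(values)
  n <- nrow(values)
  colnames(values) <- sprintf("p%d", seq_len(ncol(values)))
  cbind(
    data.frame(id = sprintf("T%02d", seq_len(n)),
               sex = rep_len(sex, n), chron_age = rep_len(age, n),
               follow_up_time = rep_len(follow_up, n),
               event = rep_len(event, n),
               cause_of_death = ifelse(rep_len(event, n) == "died",
                                       "heart disease", NA_character_),
               age_top_coded = FALSE, stringsAsFactors = FALSE),
    as.data.frame(values))
}

# Brute-force AUC by exhaustive (case, control) pair counting, ties half.
brute_force_auc <- function(scores, died) {
  cases <- scores[died]
  controls <- scores[!died]
  tot <- 0
  for (ci in cases) {
    tot <- tot + sum(ci > controls) + 0.5 * sum(ci == controls)
  }
  tot / (length(cases) * length(controls))
}
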