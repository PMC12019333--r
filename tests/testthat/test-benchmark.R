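test_that("mortality labels follow the censoring-exclusion convention", {
  coh <- toy_cohort(matrix(0, 4, 1), age = 60,
                    event = c("died", "censored", "censored", "died"))
  coh$follow_up_time <- c(5, 7, 20, 12)
  lab <- mortality_labels(coh, 10)
  expect_identical(as.vector(unclass(lab)),
                   c("died_within", "excluded_censored", "survived_beyond",
                     "survived_beyond"))
  expect_identical(attr(lab, "counts"),
                   c(died_within = 1L, survived_beyond = 2L,
                     excluded_censored = 1L))
  # all-dead (or all-survivor) label sets are rejected
  allc <- coh; allc$event <- "censored"; allc$cause_of_death <- NA
  allc$follow_up_time <- c(1, 2, 3, 4)
  expect_error(mortality_labels(allc, 10), "AUC undefined")
})

test_that("midrank AUC equals brute-force pair counting", {
  # spec-style small instance
  coh <- toy_cohort(matrix(0, 4, 1), age = 60,
                    event = c("censored", "died", "censored", "died"))
  coh$follow_up_time <- ifelse(coh$event == "died", 5, 20)
  lab <- mortality_labels(coh, 10)
  expect_equal(mortality_auc(c(1, 2, 3, 4), lab), 0.75)
  expect_equal(mortality_auc(c(3, 2, 1, 4), lab),
               brute_force_auc(c(3, 2, 1, 4), c(FALSE, TRUE, FALSE, TRUE)))
  # perfect separation and complete ties
  coh3 <- toy_cohort(matrix(0, 3, 1), age = 60,
                     event = c("died", "died", "censored"))
  coh3$follow_up_time <- ifelse(coh3$event == "died", 5, 20)
  lab3 <- mortality_labels(coh3, 10)
  expect_identical(mortality_auc(c(3, 2, 1), lab3), 1)
  expect_identical(mortality_auc(c(7, 7, 7), lab3), 0.5)
  # random instances with ties, n <= 50, against the exhaustive oracle
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    died <- runif(n) < 0.4
    if (!any(died) || all(died)) next
    s <- sample(1:8, n, replace = TRUE) + rnorm(n, sd = 0.01 * (rep %% 2))
    cohr <- toy_cohort(matrix(0, n, 1), age = 60,
                       event = ifelse(died, "died", "censored"))
    cohr$follow_up_time <- ifelse(died, 5, 20)
    labr <- mortality_labels(cohr, 10)
    expect_equal(mortality_auc(s, labr), brute_force_auc(s, died),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone score transforms", {
  coh <- default_cohort(n = 400, seed = 61)
  coh <- reference_clocks(coh, seed = 1)
  lab <- mortality_labels(coh, 10)
  a1 <- mortality_auc(coh$score_ChronAge, lab)
  a2 <- mortality_auc(exp(coh$score_ChronAge / 20), lab)
  a3 <- mortality_auc(rank(coh$score_ChronAge), lab)
  expect_identical(a1, a2)
  expect_identical(a1, a3)
})

test_that("DeLong test agrees with the independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  for (rep in 1:10) {
    n <- 120
    y <- rep(c(TRUE, FALSE), c(40, 80))
    s1 <- rnorm(n) + y * runif(1, 0.2, 1.2)
    s2 <- 0.6 * s1 + rnorm(n, sd = 0.8) + y * runif(1, 0, 0.8)
    cohr <- toy_cohort(matrix(0, n, 1), age = 60,
                       event = ifelse(y, "died", "censored"))
    cohr$follow_up_time <- ifelse(y, 5, 20)
    lab <- mortality_labels(cohr, 10)
    ours <- delong_test(s1, s2, lab)
    ref <- pROC::roc.test(
      pROC::roc(y, s1, quiet = TRUE, direction = "<"),
      pROC::roc(y, s2, quiet = TRUE, direction = "<"),
      method = "delong", paired = TRUE)
    expect_equal(ours$auc_1, as.numeric(pROC::auc(pROC::roc(y, s1,
      quiet = TRUE, direction = "<"))), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
    expect_equal(abs(ours$z), abs(unname(ref$statistic)), tolerance = 1e-9)
  }
})

test_that("DeLong degeneracies and rank invariance are handled", {
  coh <- default_cohort(n = 300, seed = 63)
  coh <- reference_clocks(coh, seed = 1)
  lab <- mortality_labels(coh, 10)
  s <- coh$score_ChronAge
  self <- delong_test(s, s, lab)
  expect_identical(self$auc_diff, 0)
  expect_identical(self$p, 1)
  expect_true(self$degenerate)
  # monotone transform: identical AUCs, zero difference
  mono <- delong_test(s, exp(s / 10), lab)
  expect_identical(mono$auc_diff, 0)
})

test_that("single-AUC DeLong variance tracks the Hanley-McNeil formula", {
  set.seed(64)
  y <- rep(c(TRUE, FALSE), each = 150)
  s <- rnorm(300) + y * 1
  cohr <- toy_cohort(matrix(0, 300, 1), age = 60,
                     event = ifelse(y, "died", "censored"))
  cohr$follow_up_time <- ifelse(y, 5, 20)
  lab <- mortality_labels(cohr, 10)
  dl <- delong_test(s, rnorm(300), lab)
  a <- dl$auc_1
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  hm <- (a * (1 - a) + 149 * (q1 - a^2) + 149 * (q2 - a^2)) / (150 * 150)
  expect_lt(abs(dl$cov[1, 1] - hm) / hm, 0.2)
})

test_that("reference clocks degrade as designed", {
  coh <- default_cohort(n = 500, seed = 65)
  c0 <- reference_clocks(coh, noise_sd = 0, seed = 1)
  expect_identical(c0$score_RandomAge, c0$score_ChronAge)
  expect_identical(c0$score_ChronAge, coh$chron_age)
  expect_true("score_CrystalAge" %in% names(c0))
  real <- coh[setdiff(names(coh), "true_death_time")]
  expect_error(reference_clocks(real, crystal = TRUE), "synthetic")
  expect_false("score_CrystalAge" %in%
                 names(reference_clocks(real, crystal = FALSE)))
  # adding noise to a sufficient predictor lowers expected AUC
  coh_age <- simulate_cohort(sim_config(n_subjects = 1500, rng_seed = 66,
                                        latent_effects = 0))
  lab <- mortality_labels(coh_age, 20)
  auc_ca <- mortality_auc(coh_age$chron_age, lab)
  auc_rand <- mean(vapply(1:40, function(s) {
    cc <- reference_clocks(coh_age, noise_sd = 10, seed = s)
    mortality_auc(cc$score_RandomAge, lab)
  }, numeric(1)))
  expect_lt(auc_rand, auc_ca)
})

test_that("quartile-stratified survival behaves on planted structure", {
  coh <- default_cohort()
  coh <- reference_clocks(coh, seed = 2)
  clk <- default_clock()
  ba <- suppressWarnings(predict(clk, coh))
  coh2 <- coh[match(ba$id, coh$id), ]
  coh2$score_BA <- ba$biological_age
  res <- stratified_km(coh2, c("score_BA", "score_ChronAge",
                               "score_CrystalAge"),
                       age_breaks = c(65, 75), horizon = 20, min_cell = 10)
  expect_s3_class(res, "stratified_km")
  km <- res$km
  # KM curves are non-increasing with valid bands
  for (cell in split(km, paste(km$clock, km$quartile))) {
    expect_true(all(diff(cell$surv) <= 1e-12))
    expect_true(all(cell$surv >= cell$lower - 1e-12 |
                      is.na(cell$lower)))
  }
  # the perfect clock's lowest quartile dominates its highest everywhere
  lo <- km[km$clock == "score_CrystalAge" & km$quartile == "lowest 25%", ]
  hi <- km[km$clock == "score_CrystalAge" & km$quartile == "highest 25%", ]
  t_grid <- c(5, 10, 15, 19)
  surv_at <- function(cell, tt) {
    i <- findInterval(tt, cell$time)
    ifelse(i == 0, 1, cell$surv[pmax(i, 1)])
  }
  expect_true(all(surv_at(lo, t_grid) >= surv_at(hi, t_grid)))
  # identical clocks compare with chisq 0, p 1
  coh2$score_BA2 <- coh2$score_BA
  res2 <- stratified_km(coh2, c("score_BA", "score_BA2"),
                        age_breaks = c(65, 75), horizon = 20, min_cell = 10)
  self_rows <- res2$tests[res2$tests$clock_1 == "score_BA" &
                            res2$tests$clock_2 == "score_BA2", ]
  expect_true(all(self_rows$chisq == 0 & self_rows$p == 1))
  # BH adjustment is per-bin, monotone in raw p and <= 1
  tt <- res$tests
  for (b in unique(tt$bin)) {
    fam <- tt[tt$bin == b, ]
    expect_equal(fam$p_adj, p.adjust(fam$p, "BH"))
    expect_true(all(fam$p_adj <= 1 & fam$p_adj >= fam$p - 1e-12))
  }
})

test_that("KM with no censoring equals the empirical survival function", {
  n <- 60
  coh <- toy_cohort(matrix(0, n, 1), age = 70, event = "died")
  set.seed(67)
  coh$follow_up_time <- sample(seq(0.5, 15, by = 0.5), n, replace = TRUE)
  coh$score_X <- rnorm(n)
  res <- stratified_km(coh, "score_X", age_breaks = c(65, 75),
                       min_cell = 5)
  km <- res$km[res$km$quartile == "lowest 25%", ]
  idx <- order(coh$score_X, coh$id)[seq_len(floor(n / 4))]
  times <- coh$follow_up_time[idx]
  emp <- vapply(km$time, function(tt) mean(times > tt), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("clock-CA correlation matches closed forms", {
  expect_equal(correlate_with_ca(c(30, 40, 50), c(30, 40, 50)),
               list(r = 1, slope = 1, intercept = 0, n = 3L),
               tolerance = 1e-12)
  ca <- c(35, 45, 55, 70)
  out <- correlate_with_ca(2 * ca + 5, ca)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$slope, 2, tolerance = 1e-12)
  expect_equal(out$intercept, 5, tolerance = 1e-12)
  expect_error(correlate_with_ca(c(1, 2, 3), c(50, 50, 50)), "variance")
  # BA = CA + noise(sd 5), CA ~ U[30,85]: r = sd(CA)/sqrt(sd(CA)^2+25)
  set.seed(68)
  ca <- runif(10000, 30, 85)
  ba <- ca + rnorm(10000, sd = 5)
  expect_equal(correlate_with_ca(ba, ca)$r,
               sd(ca) / sqrt(sd(ca)^2 + 25), tolerance = 0.02)
})
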