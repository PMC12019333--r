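test_that("planted PC-outcome signal is found, noise PCs stay blank", {
  set.seed(81)
  n <- 5000
  S <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("PC", 1:5, "M")))
  y <- rbinom(n, 1, plogis(-1 + 0.8 * S[, 1]))
  hm <- pc_outcome_heatmap(S, data.frame(planted = y),
                           mode = "disease_or_social")
  tab <- attr(hm, "table")
  p1 <- tab[tab$component == "PC1M", ]
  expect_identical(p1$provenance, "significant")
  expect_gt(p1$displayed, 0)
  expect_lt(abs(p1$raw_coef - 0.8), 0.15)
  # most pure-noise PCs are zeroed (each has a 5% false-positive chance)
  noise <- tab[tab$component != "PC1M", ]
  expect_gte(sum(noise$displayed == 0), 3)
})

test_that("truncation rules match the display conventions", {
  set.seed(82)
  n <- 4000
  S <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, paste0("PC", 1:3, "F")))
  # PC1 protective (negative log risk ratio), PC2 harmful, PC3 null
  y <- rbinom(n, 1, plogis(-1.5 - 0.6 * S[, 1] + 0.5 * S[, 2]))
  out <- data.frame(cause = y)
  hm_cod <- pc_outcome_heatmap(S, out, mode = "cause_of_death")
  tab <- attr(hm_cod, "table")
  expect_identical(tab$provenance[tab$component == "PC1F"],
                   "truncated_negative")
  expect_identical(tab$displayed[tab$component == "PC1F"], 0)
  expect_lt(tab$raw_coef[tab$component == "PC1F"], 0) # raw value retained
  expect_identical(tab$provenance[tab$component == "PC2F"], "significant")
  expect_gt(tab$displayed[tab$component == "PC2F"], 0)
  # no negative cells survive in cause-of-death mode
  expect_true(all(unclass(hm_cod) >= 0))
  # disease/social mode keeps the signed value, clipped to [-1, 2]
  hm_dis <- pc_outcome_heatmap(S, out, mode = "disease_or_social")
  tabd <- attr(hm_dis, "table")
  expect_lt(tabd$displayed[tabd$component == "PC1F"], 0)
  expect_true(all(unclass(hm_dis) >= -1 & unclass(hm_dis) <= 2))
  # insignificant cells are zeroed with provenance, raw p retained
  null_cell <- tabd[tabd$component == "PC3F", ]
  if (null_cell$p >= 0.05) {
    expect_identical(null_cell$provenance, "zeroed_by_p")
    expect_identical(null_cell$displayed, 0)
  }
})

test_that("under a global null the per-cell false-positive rate is ~5%", {
  set.seed(83)
  hits <- 0; cells <- 0
  for (rep in 1:6) {
    n <- 2000
    S <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("PC", 1:5, "M")))
    out <- as.data.frame(matrix(rbinom(n * 10, 1, 0.3), n, 10))
    hm <- pc_outcome_heatmap(S, out, mode = "disease_or_social")
    tab <- attr(hm, "table")
    hits <- hits + sum(tab$provenance == "significant")
    cells <- cells + nrow(tab)
  }
  expect_gt(hits / cells, 0.02)
  expect_lt(hits / cells, 0.09)
})

test_that("subject reports list the loading-threshold drivers", {
  L <- matrix(c(0.35, 0.09, -0.22, 0.01), 4, 1)
  clk <- make_toy_clock(loadings = cbind(L, c(0, 0, 0, 1)),
                        beta = c(1, 0), gamma = log(2) / 8)
  coh <- toy_cohort(matrix(c(2, 1, -1, 0.5), 1, 4), age = 70)
  ba <- predict(clk, coh)
  rep1 <- subject_report(ba, clk, "T01", cohort = coh,
                         loading_threshold = 0.1, min_years = 0.5)
  expect_identical(rep1$drivers$PC1M$parameter, c("p1", "p3"))
  expect_equal(rep1$drivers$PC1M$loading, c(0.35, -0.22))
  expect_equal(rep1$drivers$PC1M$value, c(2, -1))
  # contribution decomposition is carried through exactly
  expect_equal(sum(rep1$contributions) - rep1$centering_term, rep1$delta,
               tolerance = 1e-9)
  # a null subject flags nothing
  coh0 <- toy_cohort(matrix(0, 1, 4), age = 70)
  ba0 <- predict(clk, coh0)
  rep0 <- subject_report(ba0, clk, "T01", min_years = 0.5)
  expect_identical(length(rep0$drivers), 0L)
  expect_identical(rep0$delta, 0)
})

test_that("healthspan markers follow the composite definitions", {
  coh <- toy_cohort(matrix(0, 4, 1), age = 60)
  coh$dsst_score <- c(40, 55, NA, 30)
  coh$walk_time <- c(6.096, 8, -1, NA)
  coh$work_able <- c("yes", "no", NA, "yes")
  for (it in paste0("adl_i", 1:6)) coh[[it]] <- "no difficulty"
  for (it in paste0("adl_b", 1:7)) coh[[it]] <- "no difficulty"
  coh$adl_i3 <- c("some difficulty", "no difficulty", "much difficulty",
                  NA)
  coh$adl_b5 <- c("no difficulty", "unable", "no difficulty",
                  "no difficulty")
  expect_warning(mk <- healthspan_markers(coh), "non-positive walk time")
  # 6.096 m in 6.096 s -> exactly 1 m/s
  expect_identical(mk$gait_speed[1], 1)
  expect_equal(mk$gait_speed[2], 6.096 / 8)
  expect_true(is.na(mk$gait_speed[3]) && is.na(mk$gait_speed[4]))
  # iADL: "some difficulty" still counts as able; "much difficulty" not;
  # a missing item leaves the composite missing
  expect_identical(mk$iadl_able, c(TRUE, TRUE, FALSE, NA))
  # one "unable" bADL item breaks the composite
  expect_identical(mk$badl_able, c(TRUE, FALSE, TRUE, TRUE))
  expect_identical(mk$work_able, c(TRUE, FALSE, NA, TRUE))
  expect_identical(mk$cognitive, coh$dsst_score)
})

test_that("healthspan markers correlate with planted latent burden", {
  coh <- default_cohort()
  mk <- healthspan_markers(coh)
  burden <- drop(attr(coh, "latents") %*%
                   attr(coh, "config")$latent_effects)
  expect_lt(cor(mk$cognitive, burden, use = "complete.obs"), -0.1)
  expect_lt(cor(mk$gait_speed, burden, use = "complete.obs"), -0.1)
  able <- mk$iadl_able
  expect_gt(mean(burden[able %in% FALSE]), mean(burden[able %in% TRUE]))
})

test_that("group comparisons report tests and percent differences", {
  set.seed(85)
  g1 <- rnorm(100, 10, 1); g2 <- rnorm(100, 11, 1)
  out <- group_compare(c(g1, g2), rep(c("low", "high"), each = 100),
                       test = "t_test", control = rnorm(200, 10.5, 1))
  expect_lt(out$p, 0.05)
  expect_lt(out$pct_diff_1, 0)
  expect_gt(out$pct_diff_2, 0)
  # identical groups: t ~ 0, p ~ 1
  same <- group_compare(c(g1, g1), rep(c("a", "b"), each = 100))
  expect_lt(abs(same$statistic), 1e-12)
  expect_equal(same$p, 1)
  # group mean equal to control mean -> zero percent difference
  zero <- group_compare(c(g1, g2), rep(c("a", "b"), each = 100),
                        control = g1)
  expect_equal(zero$pct_diff_1, 0, tolerance = 1e-12)
  expect_error(group_compare(g1, rep("a", 100)), "2 levels")
  # wilcoxon route
  w <- group_compare(c(g1, g2), rep(c("a", "b"), each = 100),
                     test = "wilcoxon")
  expect_lt(w$p, 0.05)
  # power: 1-SD shift at n=100 per group rejects essentially always
  rej <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    group_compare(c(rnorm(100), rnorm(100, 1)),
                  rep(c("a", "b"), each = 100))$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.99)
})
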