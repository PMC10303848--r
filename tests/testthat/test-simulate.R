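test_that("simulation is byte-identical given the scenario seed", {
  scn <- default_scenario("nintedanib5", n_patients = 120L, seed = 3L)
  a <- simulate_cohort(scn)
  b <- simulate_cohort(scn)
  expect_identical(a$panel, b$panel)
  expect_identical(a$labels, b$labels)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$fills, b$fills)
})

test_that("degenerate mixtures behave as stated", {
  # constant trajectory at logit 0: overall adherent fraction ~ 0.5
  scn <- scenario(1000, 1, list(c(0)), seed = 5)
  coh <- simulate_panel(scn)
  se <- 0.5 / sqrt(1000 * 12)
  expect_lt(abs(mean(coh$panel) - 0.5), 3 * se)
  # one-hot mixing probabilities: all labels land in group 1
  scn2 <- scenario(200, c(1, 0), list(c(2), c(-2)), seed = 5)
  expect_true(all(simulate_panel(scn2)$labels == 1L))
})

test_that("realized label shares track the mixing probabilities", {
  coh <- nin5_cohort()
  scn <- coh$scenario
  shares <- tabulate(coh$labels, 5L) / scn$n_patients
  expect_true(all(abs(shares - scn$group_probs) < 0.03))
  # convergence at n = 10,000: within 3 multinomial SEs per group
  big <- simulate_panel(default_scenario("nintedanib5", n_patients = 10000L,
                                         seed = 8L))
  sh <- tabulate(big$labels, 5L) / 10000
  se <- sqrt(scn$group_probs * (1 - scn$group_probs) / 10000)
  expect_true(all(abs(sh - scn$group_probs) < 3 * se))
})

test_that("within-group monthly adherence matches the trajectory curves", {
  big <- simulate_panel(default_scenario("nintedanib5", n_patients = 10000L,
                                         seed = 8L))
  truth <- scenario_trajectory_probs(big$scenario)
  # 60 simultaneous month-by-group checks: 4 SE keeps the family-wise
  # false-alarm rate below 1 percent
  for (g in 1:5) {
    rows <- big$labels == g
    obs <- colMeans(big$panel[rows, ])
    se <- sqrt(truth[, g] * (1 - truth[, g]) / sum(rows))
    expect_true(all(abs(obs - truth[, g]) < 4 * pmax(se, 1e-3)),
                info = paste("group", g))
  }
})

test_that("covariate-driven membership shifts groups in the right direction", {
  scn <- scenario(4000, c(0.5, 0.5), list(c(3), c(-3)),
                  membership_coefs = matrix(1.5, 1, 1,
                                            dimnames = list(NULL, "risk")),
                  covariate_spec = list(risk = list(dist = "bernoulli",
                                                    p = 0.5)),
                  seed = 21)
  coh <- simulate_panel(scn)
  p_g2_risk <- mean(coh$labels[coh$covariates$risk == 1] == 2L)
  p_g2_norisk <- mean(coh$labels[coh$covariates$risk == 0] == 2L)
  expect_gt(p_g2_risk, p_g2_norisk + 0.15)
})

test_that("markov persistence increases month-to-month agreement", {
  base <- scenario(2000, 1, list(c(0)), seed = 13)
  sticky <- scenario(2000, 1, list(c(0)), markov_persistence = 0.6, seed = 13)
  agree <- function(p) mean(p[, -1] == p[, -12])
  expect_gt(agree(simulate_panel(sticky)$panel),
            agree(simulate_panel(base)$panel) + 0.1)
})

test_that("claims generation tiles adherent months exactly", {
  # fully adherent patient: 12 fills of 30 days at days 0, 30, ..., 330
  scn <- scenario(3, 1, list(c(10)), seed = 2)  # adherence prob ~ 1
  coh <- simulate_cohort(scn)
  f1 <- coh$fills[coh$fills$patient_id == 1, ]
  expect_equal(f1$day, seq(0L, 330L, by = 30L))
  expect_true(all(f1$days_supply == 30L))
  pdc <- monthly_pdc(build_supply_calendar(f1$day, f1$days_supply))
  expect_equal(pdc, rep(1, 12))
})

test_that("early-poor patients receive fills only in adherent months", {
  scn <- scenario(1, 1, list(c(0)), seed = 4)
  coh <- simulate_panel(scn)
  coh$panel[1, ] <- c(1, 1, 1, rep(0, 9))  # adherent months 1-3 only
  coh <- simulate_claims(coh$scenario, coh)
  expect_equal(coh$fills$day, c(0L, 30L, 60L))
  expect_true(all(coh$fills$days_supply == 30L))
})

test_that("panel -> claims -> adherence round trip reproduces indicators", {
  # no-short-fill configuration; the index fill makes month 1 structurally
  # adherent, months 2..T reproduce the drawn indicators exactly
  scn <- default_scenario("nintedanib5", n_patients = 150L, seed = 17L)
  coh <- simulate_cohort(scn)
  adh <- compute_adherence(coh$fills)
  expect_equal(dim(adh$panel), dim(coh$panel))
  expect_true(all(adh$panel[, 1] == 1L))
  expect_equal(unname(adh$panel[, 2:12]), unname(coh$panel[, 2:12]))
})

test_that("short fills never flip a month to adherent", {
  scn <- scenario(120, c(0.5, 0.5), list(c(3), c(-3)),
                  short_fill_prob = 1, seed = 33)
  coh <- simulate_cohort(scn)
  adh <- compute_adherence(coh$fills)
  expect_equal(unname(adh$panel[, 2:12]), unname(coh$panel[, 2:12]))
  # some non-adherent months did receive a (short) fill
  expect_gt(nrow(coh$fills), sum(coh$panel) + 10)
})

test_that("cohort tables are written as plain CSV", {
  dir <- tempfile()
  coh <- simulate_cohort(default_scenario("nintedanib5", n_patients = 20L,
                                          seed = 1L))
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(
    dir, c("covariates.csv", "panel.csv", "fills.csv", "enrollment.csv",
           "diagnoses.csv")))))
  panel <- utils::read.csv(file.path(dir, "panel.csv"))
  expect_equal(nrow(panel), 20L)
  expect_true(all(paste0("m", 1:12) %in% names(panel)))
})
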