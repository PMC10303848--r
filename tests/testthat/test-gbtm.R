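test_that("mixture log-likelihood matches hand arithmetic and symmetries", {
  panel <- matrix(rep(c(0, 1), 24), nrow = 4)  # 4 x 12
  p_half <- gbtm_params(1, list(c(0)))
  expect_equal(gbtm_loglik(p_half, panel), 48 * log(0.5), tolerance = 1e-10)
  # G = 2 with identical components equals the G = 1 value for any pi
  p2 <- gbtm_params(c(0.3, 0.7), list(c(0), c(0)))
  expect_equal(gbtm_loglik(p2, panel), 48 * log(0.5), tolerance = 1e-10)
  # degenerate mixture: pi ~ (1, 0) equals component 1 alone
  p1 <- gbtm_params(1, list(c(1, 0.5)))
  expect_equal(gbtm_loglik(gbtm_params(c(1 - 1e-12, 1e-12),
                                       list(c(1, 0.5), c(-2))), panel),
               gbtm_loglik(p1, panel), tolerance = 1e-6)
})

test_that("log-likelihood equals a brute-force product oracle on tiny panels", {
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(2:12, 1); Tm <- sample(2:3, 1); G <- sample(1:3, 1)
    panel <- matrix(rbinom(n * Tm, 1, 0.5), n, Tm)
    pi <- as.numeric(stats::rgamma(G, 2)); pi <- pi / sum(pi)
    beta <- lapply(seq_len(G), function(g) rnorm(sample(1:2, 1), 0, 1))
    params <- gbtm_params(pi, beta)
    probs <- sapply(beta, function(b) {
      plogis(drop(month_basis(seq_len(Tm), length(b) - 1L, Tm) %*% b))
    })
    probs <- matrix(probs, nrow = Tm)
    expect_equal(gbtm_loglik(params, panel),
                 brute_loglik(pi, probs, panel), tolerance = 1e-10)
  }
})

test_that("posteriors follow Bayes rule", {
  # 1 patient, G = 2, T = 1: p = (0.9, 0.1), y = 1 -> posterior (0.9, 0.1)
  params <- gbtm_params(c(0.5, 0.5), list(qlogis(0.9), qlogis(0.1)))
  post <- gbtm_posterior(params, matrix(1, 1, 1))
  expect_equal(as.numeric(post), c(0.9, 0.1), tolerance = 1e-12)
  # identical components: every row equals pi
  panel <- matrix(rbinom(60, 1, 0.5), 5)
  same <- gbtm_params(c(0.25, 0.75), list(c(0.3), c(0.3)))
  post2 <- gbtm_posterior(same, panel)
  expect_true(all(abs(sweep(post2, 2, c(0.25, 0.75))) < 1e-12))
  # rows always sum to 1
  expect_equal(rowSums(post2), rep(1, 5))
})

test_that("BIC uses the trajectory-modeling convention", {
  expect_equal(gbtm_bic(-33.2711, 1, 4), -33.2711 - 0.5 * log(4))
  # penalty monotonicity at equal logL
  expect_lt(gbtm_bic(-100, 5, 200), gbtm_bic(-100, 4, 200))
  # k = 0 leaves logL unchanged
  expect_equal(gbtm_bic(-100, 0, 200), -100)
  # alternative N convention penalizes more at T = 12
  expect_lt(gbtm_bic(-100, 4, 200, n_convention = "observations"),
            gbtm_bic(-100, 4, 200))
})

test_that("single-group order-0 fit recovers the closed-form Bernoulli MLE", {
  set.seed(12)
  panel <- matrix(rbinom(50 * 12, 1, 0.75), 50)
  frac <- mean(panel)
  fit <- fit_gbtm(panel, trajectory_spec(1, 0), starts = 2, seed = 1)
  expect_equal(fit$params$beta[[1]], qlogis(frac), tolerance = 1e-6)
  expect_equal(fit$params$pi, 1)
  # wald on an order-0 group targets its intercept
  wt <- wald_highest_terms(fit)
  expect_equal(wt$coef, fit$params$beta[[1]])
  expect_true(wt$p < 0.05)
})

test_that("well-separated two-group truth is recovered within 3 SE", {
  scn <- default_scenario("two_group_easy", seed = 23)
  coh <- simulate_panel(scn)
  fit <- fit_gbtm(coh$panel, trajectory_spec(2, 0), starts = 5, seed = 2)
  ord <- order(-fit$params$pi)  # group 1 = larger share (true 0.6, logit +3)
  pi_hat <- fit$params$pi[ord]
  mc_se <- sqrt(0.6 * 0.4 / 1000)
  expect_lt(abs(pi_hat[1] - 0.6), 3 * mc_se + 0.01)
  b <- c(fit$params$beta[[ord[1]]], fit$params$beta[[ord[2]]])
  se <- fit$se[paste0("beta", ord, "_0")]
  expect_lt(abs(b[1] - 3), 3 * se[1])
  expect_lt(abs(b[2] + 3), 3 * se[2])
  expect_true(fit$convergence$converged)
})

test_that("relabeling groups leaves logL and BIC unchanged", {
  set.seed(31)
  panel <- matrix(rbinom(40 * 12, 1, rep(c(0.9, 0.2), each = 240)), 40,
                  byrow = FALSE)
  params <- gbtm_params(c(0.55, 0.45), list(c(2, 0.4), c(-1.5)))
  flipped <- gbtm_params(c(0.45, 0.55), list(c(-1.5), c(2, 0.4)))
  expect_equal(gbtm_loglik(params, panel), gbtm_loglik(flipped, panel),
               tolerance = 1e-12)
})

test_that("EM runs warning-free (monotone) and is deterministic given seed", {
  coh <- simulate_panel(default_scenario("two_group_easy",
                                         n_patients = 300L, seed = 9))
  expect_no_warning(f1 <- fit_gbtm(coh$panel, trajectory_spec(2, 1),
                                   starts = 4, seed = 77, se = FALSE))
  f2 <- fit_gbtm(coh$panel, trajectory_spec(2, 1), starts = 4, seed = 77,
                 se = FALSE)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$params, f2$params)
  # posterior rows sum to 1, pi sums to 1
  expect_equal(unname(rowSums(f1$posteriors)), rep(1, 300),
               tolerance = 1e-10)
  expect_equal(sum(f1$params$pi), 1, tolerance = 1e-12)
  expect_equal(f1$bic, gbtm_bic(f1$loglik, f1$k, 300))
})

test_that("wald tests use the normal reference", {
  fake <- structure(list(
    spec = trajectory_spec(2, c(1, 0)),
    params = gbtm_params(c(0.5, 0.5), list(c(1, 0.196), c(0))),
    se = c(alpha2 = 0.1, beta1_0 = 0.2, beta1_1 = 0.1, beta2_0 = 0.3),
    n_months = 12L
  ), class = "adtraj_gbtm")
  wt <- wald_highest_terms(fake)
  # z = 1.96 -> p ~ 0.05
  expect_equal(wt$z[1], 1.96, tolerance = 1e-12)
  expect_equal(wt$p[1], 0.05, tolerance = 1e-3)
  # exact zero coefficient -> p = 1
  expect_equal(wt$p[2], 1)
  # singular information -> p = 1 with warning
  fake$se[["beta2_0"]] <- NA_real_
  expect_warning(wt2 <- wald_highest_terms(fake), "singular")
  expect_equal(wt2$p[2], 1)
})

test_that("panel validation rejects bad input", {
  expect_error(fit_gbtm(matrix(numeric(0), 0, 12), trajectory_spec(1, 0)),
               "empty")
  expect_error(fit_gbtm(matrix(c(0, 2), 1, 2), trajectory_spec(1, 0)), "0/1")
  expect_error(fit_gbtm(matrix(1, 1, 12), trajectory_spec(2, 0)),
               "at least G")
})
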