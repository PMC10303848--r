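simplex_rows <- function(n, G, seed = 1) {
  set.seed(seed)
  m <- matrix(rgamma(n * G, 1.5), n, G)
  m / rowSums(m)
}

test_that("intercept-only fit reproduces the share column means", {
  S <- simplex_rows(80, 3, seed = 2)
  X <- matrix(1, 80, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_fmlogit(S, X)
  expect_true(fit$converged)
  expect_equal(unname(fit$fitted[1, ]), unname(colMeans(S)),
               tolerance = 1e-8)
  # fitted mean rows always sum to 1
  expect_equal(rowSums(fit$fitted), rep(1, 80), tolerance = 1e-12)
})

test_that("one-hot shares reproduce ordinary logistic regression (G = 2)", {
  set.seed(14)
  n <- 50
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.4 + 0.9 * x))
  S <- cbind(1 - y, y)
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_fmlogit(S, X, ref_group = 1L)
  oracle <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$coef["group2", ]), unname(coef(oracle)),
               tolerance = 1e-6)
  # and the model-based SEs agree with glm's
  se_fm <- sqrt(diag(fit$vcov_model))
  expect_equal(unname(se_fm), unname(sqrt(diag(vcov(oracle)))),
               tolerance = 1e-4)
})

test_that("known coefficients are recovered within 3 robust SE", {
  set.seed(99)
  n <- 2000; G <- 3
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  gamma_true <- rbind(group2 = c(0.3, 0.7, -0.5),
                      group3 = c(-0.4, -0.6, 0.8))
  eta <- cbind(0, X %*% t(gamma_true))
  mu <- exp(eta) / rowSums(exp(eta))
  # fractional outcomes: Dirichlet-like noise around the mean simplex
  S <- t(vapply(seq_len(n), function(i) {
    v <- rgamma(G, shape = 25 * mu[i, ])
    v / sum(v)
  }, numeric(G)))
  fit <- fit_fmlogit(S, X)
  se <- sqrt(diag(fit$vcov_robust))
  est <- as.vector(t(fit$coef))
  expect_true(all(abs(est - as.vector(t(gamma_true))) < 3 * se))
})

test_that("robust and model-based SEs agree under multinomial sampling", {
  set.seed(7)
  n <- 2000
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  gamma_true <- rbind(group2 = c(0.2, 0.5), group3 = c(-0.3, -0.4))
  eta <- cbind(0, X %*% t(gamma_true))
  mu <- exp(eta) / rowSums(exp(eta))
  lab <- vapply(seq_len(n), function(i) {
    sample.int(3L, 1L, prob = mu[i, ])
  }, integer(1))
  S <- diag(3)[lab, ]
  fit <- fit_fmlogit(S, X)
  r <- sqrt(diag(fit$vcov_robust)) / sqrt(diag(fit$vcov_model))
  expect_true(all(r > 0.8 & r < 1.2))
})

test_that("duplicating every row halves the variance, not the estimate", {
  S <- simplex_rows(60, 3, seed = 5)
  set.seed(6)
  X <- cbind(`(Intercept)` = 1, x = rnorm(60))
  f1 <- fit_fmlogit(S, X)
  f2 <- fit_fmlogit(rbind(S, S), rbind(X, X))
  expect_equal(f2$coef, f1$coef, tolerance = 1e-6)
  expect_equal(sqrt(diag(f2$vcov_robust)),
               sqrt(diag(f1$vcov_robust)) / sqrt(2), tolerance = 1e-4)
})

test_that("reference-group switch shifts coefficients, not fitted means", {
  S <- simplex_rows(100, 3, seed = 8)
  set.seed(9)
  X <- cbind(`(Intercept)` = 1, x = rnorm(100))
  f1 <- fit_fmlogit(S, X, ref_group = 1L)
  f2 <- fit_fmlogit(S, X, ref_group = 2L)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-6)
  # gamma under ref 2 = gamma under ref 1 minus group-2 coefficients
  expect_equal(unname(f2$coef["group3", ]),
               unname(f1$coef["group3", ] - f1$coef["group2", ]),
               tolerance = 1e-6)
})

test_that("design validation names offending columns", {
  S <- simplex_rows(30, 2, seed = 11)
  X_const <- cbind(`(Intercept)` = 1, bad = rep(2, 30))
  expect_error(fit_fmlogit(S, X_const), "bad")
  set.seed(3)
  x <- rnorm(30)
  X_coll <- cbind(`(Intercept)` = 1, x = x, x2 = 2 * x)
  expect_error(fit_fmlogit(S, X_coll), "x2")
  expect_error(fit_fmlogit(S * 2, matrix(1, 30, 1)), "sum to 1|\\[0, 1\\]")
  expect_error(fit_fmlogit(cbind(S[, 1] + 0.6, S[, 2] - 0.6),
                           matrix(1, 30, 1)), "sum to 1|\\[0, 1\\]")
})

test_that("AOR table matches closed-form transformations", {
  S <- simplex_rows(120, 2, seed = 12)
  set.seed(13)
  X <- cbind(`(Intercept)` = 1, x = rnorm(120))
  fit <- fit_fmlogit(S, X)
  tab <- aor_table(fit)
  expect_equal(tab$aor, exp(tab$coef), tolerance = 1e-12)
  z <- qnorm(0.975)
  expect_equal(tab$ci_low, exp(tab$coef - z * tab$se), tolerance = 1e-12)
  # CI excludes 1 exactly when p < 0.05
  excl <- tab$ci_low > 1 | tab$ci_high < 1
  expect_equal(excl, tab$p < 0.05)
  # worked numbers: gamma = ln 2, SE = 0.1
  ci <- exp(log(2) + c(-1, 1) * z * 0.1)
  expect_equal(ci, c(1.6441, 2.4331), tolerance = 1e-4)
})

test_that("membership_design expands factors and missing indicators", {
  cov <- data.frame(patient_id = 1:6,
                    age = c(70, 75, NA, 80, 72, 71),
                    region = c("N", "S", "S", "W", "N", "W"))
  X <- membership_design(cov, c("age", "region"))
  expect_true(all(c("(Intercept)", "age", "age_missing", "regionS",
                    "regionW") %in% colnames(X)))
  expect_equal(unname(X[3, "age_missing"]), 1)
  expect_equal(unname(X[3, "age"]), 0)
  expect_error(membership_design(cov, "nope"), "nope")
})
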