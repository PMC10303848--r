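test_that("group assignment is argmax with lowest-index tie-break", {
  post <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8))
  a <- assign_groups(post)
  expect_equal(a$labels, c(1L, 1L, 2L))
  expect_equal(a$ties, c(FALSE, TRUE, FALSE))
  onehot <- diag(3)
  expect_equal(assign_groups(onehot)$labels, 1:3)
})

test_that("APP matches hand arithmetic and boundary cases", {
  onehot <- diag(2)[c(1, 1, 2), ]
  expect_equal(as.numeric(app(onehot)), c(1, 1))
  post <- rbind(c(0.8, 0.2), c(0.9, 0.1))
  expect_equal(as.numeric(app(post))[1], 0.85)
  unif <- matrix(0.5, 4, 2)
  a <- app(unif)  # everything assigned to group 1 by tie-break
  expect_equal(as.numeric(a), c(0.5, NA))
  expect_equal(attr(a, "empty_groups"), 2L)
})

test_that("OCC follows its definition", {
  expect_equal(as.numeric(occ(0.3, 0.3)), 1)  # no better than chance
  expect_equal(as.numeric(occ(0.9, 0.3)), 21, tolerance = 1e-12)
  # the published smallest APP with an illustrative share
  expect_equal(as.numeric(occ(0.845, 0.104)),
               (0.845 / 0.155) / (0.104 / 0.896), tolerance = 1e-12)
  expect_equal(as.numeric(occ(0.845, 0.104)), 46.97, tolerance = 1e-3)
  # boundary values are capped and flagged
  capped <- occ(c(1, 0.5), c(0.5, 0.5))
  expect_equal(attr(capped, "capped"), 1L)
  expect_true(is.finite(capped[1]))
})

test_that("OCC is monotone in APP and anti-monotone in pi", {
  apps <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(as.numeric(occ(apps, rep(0.3, length(apps))))) > 0))
  pis <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(as.numeric(occ(rep(0.7, length(pis)), pis))) < 0))
})

test_that("relative entropy spans its closed-form anchors", {
  expect_equal(relative_entropy(diag(4)[c(1, 2, 3, 4, 1), ]), 1)
  expect_equal(relative_entropy(matrix(1 / 3, 6, 3)), 0, tolerance = 1e-12)
  post <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  h <- -(0.9 * log(0.9) + 0.1 * log(0.1)) + log(2)
  expect_equal(relative_entropy(post), 1 - h / (2 * log(2)))
  expect_equal(relative_entropy(post), 0.2656, tolerance = 1e-3)
  # single group: 1 by convention, flagged
  e1 <- relative_entropy(matrix(1, 5, 1))
  expect_equal(as.numeric(e1), 1)
  expect_true(attr(e1, "single_group"))
  # invariant under relabeling
  expect_equal(relative_entropy(post), relative_entropy(post[, 2:1]))
})

test_that("trajectory tables reconcile observed and fitted curves", {
  # perfect-fit synthetic: component probabilities 0/1 reproduce the data
  params <- gbtm_params(c(0.5, 0.5), list(c(20), c(-20)))
  panel <- rbind(matrix(1, 3, 12), matrix(0, 3, 12))
  post <- gbtm_posterior(params, panel)
  tt <- trajectory_tables(panel, post, params)
  for (g in 1:2) {
    s <- tt$summary[tt$summary$group == g, ]
    expect_equal(s$observed, s$fitted, tolerance = 1e-4)
  }
  expect_equal(nrow(tt$spaghetti), 6 * 12)
  expect_equal(length(tt$empty_groups), 0L)
  # empty group is reported with a flag
  post1 <- cbind(rep(1, 6), rep(0, 6))
  tt2 <- trajectory_tables(panel, post1, params)
  expect_equal(tt2$empty_groups, 2L)
  expect_true(all(is.na(tt2$summary$observed[tt2$summary$group == 2])))
})

test_that("model_diagnostics passes the adequacy thresholds when separation is strong", {
  coh <- simulate_panel(default_scenario("two_group_easy",
                                         n_patients = 500L, seed = 41))
  fit <- fit_gbtm(coh$panel, trajectory_spec(2, 0), starts = 3, seed = 5,
                  se = FALSE)
  d <- model_diagnostics(fit, coh$panel)
  expect_true(all(d$pass))
  expect_equal(sum(d$assigned_share), 1)
  expect_equal(as.numeric(d$occ),
               as.numeric(occ(d$app, d$pi)), tolerance = 1e-12)
  # assigned-share variant is exposed as an option
  d2 <- model_diagnostics(fit, coh$panel, pi_source = "assigned")
  expect_equal(as.numeric(d2$occ),
               as.numeric(occ(d$app, d$assigned_share)), tolerance = 1e-12)
})
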