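# Independent day-by-day stockpiling oracle: pills accumulate into a stock
# on each fill day and one is consumed per covered day. Used to validate
# the pointer-based supply calendar.
brute_calendar <- function(day, days_supply, horizon = 360L) {
  covered <- rep(FALSE, horizon)
  stock <- 0L
  add <- tapply(days_supply, day, sum)
  for (d in 0:(horizon - 1L)) {
    key <- as.character(d)
    if (!is.na(add[key])) stock <- stock + add[[key]]
    if (stock > 0L) {
      covered[d + 1L] <- TRUE
      stock <- stock - 1L
    }
  }
  covered
}

# Brute-force mixture log-likelihood: explicit per-group products, no log
# space. Only safe for tiny panels.
brute_loglik <- function(pi, probs, panel) {
  # probs: T x G per-month success probabilities
  n <- nrow(panel)
  ll <- 0
  for (i in seq_len(n)) {
    li <- 0
    for (g in seq_along(pi)) {
      y <- panel[i, ]
      li <- li + pi[g] * prod(probs[, g]^y * (1 - probs[, g])^(1 - y))
    }
    ll <- ll + log(li)
  }
  ll
}

random_fill_set <- function(max_fills = 8L, horizon = 360L) {
  k <- sample.int(max_fills, 1L)
  list(day = sample(0:(horizon + 30L), k, replace = TRUE),
       days_supply = sample(1:90, k, replace = TRUE))
}

# Seeded medium-size fits reused across test files (built lazily once).
.adtraj_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .adtraj_cache)) {
    assign(key, force(expr), .adtraj_cache)
  }
  get(key, .adtraj_cache)
}

nin5_cohort <- function() cached("nin5_cohort", {
  simulate_panel(default_scenario("nintedanib5", seed = 42))
})

# Stage-1 grid search on the seeded default cohort at reduced restarts;
# shared by the acceptance criteria (model count, share recovery, adequacy).
nin5_grid <- function() cached("nin5_grid", {
  grid_search(nin5_cohort()$panel, starts = 3L, seed = 11L)
})
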