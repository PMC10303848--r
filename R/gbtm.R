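#' Trajectory model specification
#'
#' @param G number of latent groups (>= 1).
#' @param orders per-group polynomial order(s) in 0..5; a scalar is
#'   recycled to all groups.
#' @return object of class \code{"adtraj_spec"}.
#' @export
trajectory_spec <- function(G, orders) {
  G <- as.integer(G)
  if (G < 1L) stop("G must be >= 1", call. = FALSE)
  if (length(orders) == 1L) orders <- rep(orders, G)
  orders <- as.integer(orders)
  if (length(orders) != G) stop("orders must have length G", call. = FALSE)
  if (any(orders < 0L) || any(orders > 5L)) {
    stop("polynomial orders must lie in 0..5", call. = FALSE)
  }
  structure(list(G = G, orders = orders), class = "adtraj_spec")
}

# free-parameter count: G-1 mixing logits + one coefficient per polynomial
# term per group
.spec_k <- function(spec) (spec$G - 1L) + sum(spec$orders + 1L)

#' Trajectory model parameters
#'
#' @param pi mixing probabilities (simplex of length G).
#' @param beta list of per-group coefficient vectors on the standardized
#'   month basis; vector g has length \code{orders[g] + 1}.
#' @return object of class \code{"adtraj_params"}.
#' @export
gbtm_params <- function(pi, beta) {
  pi <- as.numeric(pi)
  if (!is.list(beta)) beta <- list(beta)
  if (length(pi) != length(beta)) stop("pi and beta lengths differ", call. = FALSE)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("pi must be a simplex", call. = FALSE)
  }
  structure(list(pi = pi / sum(pi), beta = lapply(beta, as.numeric)),
            class = "adtraj_params")
}

# per-month success probabilities, T x G, from clipped linear predictors
.traj_probs <- function(beta, n_months, clip = 12) {
  vapply(beta, function(b) {
    X <- month_basis(seq_len(n_months), length(b) - 1L, n_months)
    .inv_logit(.clip(drop(X %*% b), clip))
  }, numeric(n_months))
}

# N x G matrix of per-group Bernoulli log-densities of each patient's row
.component_logdens <- function(beta, panel, clip = 12) {
  p <- .traj_probs(beta, ncol(panel), clip)
  panel %*% log(p) + (1 - panel) %*% log(1 - p)
}

#' Mixture log-likelihood of an adherence panel
#'
#' \code{sum_i log sum_g pi_g prod_t p_gt^y_it (1 - p_gt)^(1 - y_it)},
#' computed in log space with max-shift stabilization. Linear predictors
#' are clipped at \code{+-clip} so separated months (e.g. a structurally
#' all-adherent first month) keep the likelihood bounded.
#'
#' @param params [gbtm_params()].
#' @param panel N x T 0/1 matrix.
#' @param clip linear-predictor clip bound.
#' @return scalar log-likelihood.
#' @export
gbtm_loglik <- function(params, panel, clip = 12) {
  panel <- .assert_binary_panel(panel)
  logf <- .component_logdens(params$beta, panel, clip)
  sum(.row_logsumexp(sweep(logf, 2L, log(params$pi), `+`)))
}

#' Posterior group-membership probabilities
#'
#' Bayes weights \code{p_ig proportional to pi_g f_g(y_i)}; rows sum to 1.
#'
#' @inheritParams gbtm_loglik
#' @return N x G matrix.
#' @export
gbtm_posterior <- function(params, panel, clip = 12) {
  panel <- .assert_binary_panel(panel)
  logf <- sweep(.component_logdens(params$beta, panel, clip), 2L,
                log(params$pi), `+`)
  post <- exp(logf - .row_logsumexp(logf))
  post / rowSums(post)
}

#' BIC under the trajectory-modeling convention
#'
#' \code{BIC = logL - (k/2) log(N)} with N = number of patients by default
#' (larger is better). The alternative convention counting patient-months
#' as N is available via \code{n_convention = "observations"}.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param n_patients,n_months panel dimensions.
#' @param n_convention "patients" (default) or "observations".
#' @return scalar BIC (larger is better).
#' @export
gbtm_bic <- function(loglik, k, n_patients, n_months = 12L,
                     n_convention = c("patients", "observations")) {
  n_convention <- match.arg(n_convention)
  N <- if (n_convention == "patients") n_patients else n_patients * n_months
  loglik - (k / 2) * log(N)
}

# ---------------------------------------------------------------------------
# M-step: ridge-penalized weighted logistic fit on the 12 aggregated month
# observations (posterior-weighted successes / trials), Newton with step
# halving on the clipped objective. Clipping makes the objective flat beyond
# +-clip, which keeps separated columns (all successes) finite and stable.
# ---------------------------------------------------------------------------
.wlogit_fit <- function(X, s, n_trials, beta0, ridge = 1e-8, clip = 12,
                        max_iter = 100L, tol = 1e-10) {
  log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
  obj <- function(b) {
    etac <- .clip(drop(X %*% b), clip)
    sum(s * etac - n_trials * log1pexp(etac)) - 0.5 * ridge * sum(b^2)
  }
  b <- beta0
  f <- obj(b)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    act <- as.numeric(abs(eta) < clip)
    mu <- .inv_logit(.clip(eta, clip))
    grad <- drop(crossprod(X, (s - n_trials * mu) * act)) - ridge * b
    w <- act * n_trials * mu * (1 - mu)
    H <- crossprod(X * sqrt(w)) + diag(ridge + 1e-12, length(b))
    step <- tryCatch(solve(H, grad), error = function(e) grad / max(diag(H)))
    lam <- 1
    repeat {
      bn <- b + lam * step
      fn <- obj(bn)
      if (fn >= f - 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    if (fn < f) break  # no improving step found
    conv <- abs(fn - f) < tol * (abs(f) + 1e-8)
    b <- bn; f <- fn
    if (conv) break
  }
  b
}

# Initial responsibilities. Restarts cycle through three strategies so the
# EM explores distinct basins: equal-frequency bins of jittered adherence
# row sums (captures overall level), k-means on the 0/1 month patterns with
# random centers (captures shape, e.g. when adherence drops), and fully
# random responsibilities.
.init_resp <- function(panel, G, method = c("rowsum", "kmeans", "random")) {
  method <- match.arg(method)
  n <- nrow(panel)
  if (G == 1L) return(matrix(1, n, 1L))
  soft_onehot <- function(bin) {
    W <- matrix(0.15 / G, n, G)
    W[cbind(seq_len(n), bin)] <- W[cbind(seq_len(n), bin)] + 0.85
    W * matrix(stats::runif(n * G, 0.9, 1.1), n, G)
  }
  if (method == "rowsum") {
    rs <- rowSums(panel) + stats::runif(n, 0, 0.5)
    qs <- stats::quantile(rs, probs = seq(0, 1, length.out = G + 1L))
    qs[1] <- -Inf; qs[G + 1L] <- Inf
    return(soft_onehot(cut(rs, qs, labels = FALSE)))
  }
  if (method == "kmeans") {
    km <- tryCatch(
      stats::kmeans(panel + matrix(stats::rnorm(n * ncol(panel), 0, 0.05),
                                   n, ncol(panel)),
                    centers = G, nstart = 1L, iter.max = 25L),
      error = function(e) NULL)
    if (!is.null(km)) return(soft_onehot(km$cluster))
  }
  W <- matrix(stats::rgamma(n * G, 1), n, G)
  W / rowSums(W)
}

# pack/unpack free parameters: (G-1) mixing logits (group 1 reference) then
# stacked trajectory coefficients
.pack_theta <- function(params) {
  c(log(params$pi[-1] / params$pi[1]), unlist(params$beta))
}
.unpack_theta <- function(theta, spec) {
  G <- spec$G
  alpha <- c(0, theta[seq_len(G - 1L)])
  pi <- exp(alpha - max(alpha)); pi <- pi / sum(pi)
  beta <- vector("list", G)
  off <- G - 1L
  for (g in seq_len(G)) {
    d <- spec$orders[g] + 1L
    beta[[g]] <- theta[off + seq_len(d)]
    off <- off + d
  }
  gbtm_params(pi, beta)
}

.theta_names <- function(spec) {
  c(if (spec$G > 1L) paste0("alpha", 2:spec$G),
    unlist(lapply(seq_len(spec$G), function(g) {
      paste0("beta", g, "_", 0:spec$orders[g])
    })))
}

#' Fit a group-based trajectory model by EM
#'
#' Maximum likelihood for the G-component mixture in which group membership
#' follows an intercept-only multinomial logit and, within group, monthly
#' binary adherence indicators follow a logistic polynomial in the
#' standardized month index. The E-step computes posterior membership
#' probabilities; the M-step updates mixing probabilities as posterior
#' means and each group's polynomial by a posterior-weighted
#' iteratively-reweighted logistic solve (with a tiny ridge, default 1e-8)
#' on the aggregated month counts. The best of \code{starts} random
#' initializations is retained; the run is deterministic given \code{seed}.
#'
#' @param panel N x T 0/1 adherence matrix.
#' @param spec a [trajectory_spec()].
#' @param starts number of random restarts (default 10).
#' @param seed RNG seed for initialization.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param ridge ridge added to each weighted logistic solve.
#' @param clip linear-predictor clip bound (see [gbtm_loglik()]).
#' @param se compute standard errors from the numerically differentiated
#'   observed information of the full mixture log-likelihood (needed for
#'   [wald_highest_terms()]; skip in large grid searches for speed).
#' @param n_convention BIC sample-size convention, see [gbtm_bic()].
#' @return object of class \code{"adtraj_gbtm"}: spec, params, loglik, bic,
#'   posteriors, labels, se / vcov (when requested), and a convergence
#'   record (per-start iterations, converged flags, best start).
#' @export
fit_gbtm <- function(panel, spec, starts = 10L, seed = 1L, tol = 1e-7,
                     max_iter = 500L, ridge = 1e-8, clip = 12, se = TRUE,
                     n_convention = "patients") {
  panel <- .assert_binary_panel(panel)
  stopifnot(inherits(spec, "adtraj_spec"))
  n <- nrow(panel); Tm <- ncol(panel); G <- spec$G
  if (n < G) stop("need at least G patients", call. = FALSE)
  Xg <- lapply(spec$orders, function(d) month_basis(seq_len(Tm), d, Tm))

  set.seed(seed)
  best <- NULL
  conv_rec <- data.frame(start = seq_len(starts), loglik = NA_real_,
                         iterations = NA_integer_, converged = FALSE)
  init_cycle <- c("rowsum", rep(c("kmeans", "random"), length.out = max(0L, starts - 1L)))
  for (s in seq_len(starts)) {
    W <- .init_resp(panel, G, init_cycle[s])
    W <- W / rowSums(W)
    pi <- colMeans(W)
    beta <- lapply(seq_len(G), function(g) numeric(spec$orders[g] + 1L))
    # first M-step from initial responsibilities
    S <- crossprod(W, panel)                 # G x T weighted successes
    ntr <- colSums(W)
    for (g in seq_len(G)) {
      beta[[g]] <- .wlogit_fit(Xg[[g]], S[g, ], rep(ntr[g], Tm), beta[[g]],
                               ridge, clip)
    }
    params <- gbtm_params(pi, beta)
    ll_old <- -Inf
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      logf <- sweep(.component_logdens(params$beta, panel, clip), 2L,
                    log(params$pi), `+`)
      lse <- .row_logsumexp(logf)
      ll <- sum(lse)
      W <- exp(logf - lse)
      if (is.finite(ll_old) && ll < ll_old - 1e-6) {
        warning("EM log-likelihood decreased; stopping this start")
        break
      }
      if (is.finite(ll_old) &&
          abs(ll - ll_old) < tol * (abs(ll_old) + 1e-8)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      pi <- colMeans(W)
      pi <- pmax(pi, 1e-12); pi <- pi / sum(pi)
      S <- crossprod(W, panel)
      ntr <- colSums(W)
      for (g in seq_len(G)) {
        beta[[g]] <- .wlogit_fit(Xg[[g]], S[g, ], rep(ntr[g], Tm),
                                 params$beta[[g]], ridge, clip)
      }
      params <- gbtm_params(pi, beta)
    }
    ll_final <- gbtm_loglik(params, panel, clip)
    conv_rec$loglik[s] <- ll_final
    conv_rec$iterations[s] <- it
    conv_rec$converged[s] <- converged
    if (is.null(best) || ll_final > best$loglik + 1e-9) {
      best <- list(params = params, loglik = ll_final, start = s,
                   converged = converged)
    }
  }

  post <- gbtm_posterior(best$params, panel, clip)
  k <- .spec_k(spec)
  fit <- structure(list(
    spec = spec,
    params = best$params,
    loglik = best$loglik,
    bic = gbtm_bic(best$loglik, k, n, Tm, n_convention),
    k = k,
    n = n,
    n_months = Tm,
    posteriors = post,
    labels = assign_groups(post)$labels,
    clip = clip,
    convergence = list(record = conv_rec, best_start = best$start,
                       converged = best$converged),
    se = NULL, vcov = NULL
  ), class = "adtraj_gbtm")
  if (se) fit <- add_gbtm_se(fit, panel)
  fit
}

#' Standard errors from the observed information
#'
#' Numerically differentiates the full mixture log-likelihood at the
#' optimum (central differences) and inverts the observed information.
#' A singular or indefinite information matrix is flagged; affected
#' standard errors are returned as NA.
#'
#' @param fit an \code{"adtraj_gbtm"}.
#' @param panel the panel the model was fit to.
#' @return the fit with \code{se} (named vector), \code{vcov}, and
#'   \code{se_singular} flag filled in.
#' @export
add_gbtm_se <- function(fit, panel) {
  panel <- .assert_binary_panel(panel)
  spec <- fit$spec
  theta <- .pack_theta(fit$params)
  f <- function(th) gbtm_loglik(.unpack_theta(th, spec), panel, fit$clip)
  p <- length(theta)
  h <- 1e-4 * pmax(abs(theta), 1)
  H <- matrix(NA_real_, p, p)
  f0 <- f(theta)
  for (j in seq_len(p)) {
    ej <- numeric(p); ej[j] <- h[j]
    H[j, j] <- (f(theta + ej) - 2 * f0 + f(theta - ej)) / h[j]^2
    if (j > 1L) for (k in seq_len(j - 1L)) {
      ek <- numeric(p); ek[k] <- h[k]
      H[j, k] <- H[k, j] <-
        (f(theta + ej + ek) - f(theta + ej - ek) -
           f(theta - ej + ek) + f(theta - ej - ek)) / (4 * h[j] * h[k])
    }
  }
  nm <- .theta_names(spec)
  dimnames(H) <- list(nm, nm)
  V <- tryCatch(solve(-H), error = function(e) NULL)
  singular <- is.null(V) || any(!is.finite(diag(V))) || any(diag(V) <= 0)
  if (singular) {
    fit$se <- stats::setNames(rep(NA_real_, p), nm)
    fit$vcov <- NULL
  } else {
    fit$se <- stats::setNames(sqrt(diag(V)), nm)
    fit$vcov <- V
  }
  fit$se_singular <- singular
  fit
}

#' Wald tests on each group's highest-order polynomial coefficient
#'
#' For each group the highest retained term (the intercept for an order-0
#' group) is tested against zero with \code{z = coef / SE} and a two-sided
#' normal p-value. Missing standard errors (singular information) yield
#' p = 1 with a warning, i.e. are treated as non-significant.
#'
#' @param fit a fitted \code{"adtraj_gbtm"} with standard errors.
#' @return data.frame (group, order, coef, se, z, p).
#' @export
wald_highest_terms <- function(fit) {
  stopifnot(inherits(fit, "adtraj_gbtm"))
  if (is.null(fit$se)) stop("fit has no standard errors; rerun with se = TRUE",
                            call. = FALSE)
  G <- fit$spec$G
  out <- data.frame(group = seq_len(G), order = fit$spec$orders,
                    coef = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_)
  for (g in seq_len(G)) {
    b <- fit$params$beta[[g]]
    nm <- paste0("beta", g, "_", fit$spec$orders[g])
    out$coef[g] <- b[length(b)]
    out$se[g] <- fit$se[[nm]]
    if (is.na(out$se[g]) || out$se[g] <= 0) {
      warning(sprintf("group %d: singular information; highest term treated as non-significant", g))
      out$p[g] <- 1
    } else {
      out$z[g] <- out$coef[g] / out$se[g]
      out$p[g] <- 2 * stats::pnorm(-abs(out$z[g]))
    }
  }
  out
}

#' @export
print.adtraj_gbtm <- function(x, ...) {
  cat(sprintf("Group-based trajectory model: G = %d, orders = (%s)\n",
              x$spec$G, paste(x$spec$orders, collapse = ", ")))
  cat(sprintf("  logL = %.4f  k = %d  BIC = %.4f  N = %d\n",
              x$loglik, x$k, x$bic, x$n))
  cat("  pi:", paste(sprintf("%.4f", x$params$pi), collapse = " "), "\n")
  cat(sprintf("  best start %d (%s)\n", x$convergence$best_start,
              if (x$convergence$converged) "converged" else "not converged"))
  invisible(x)
}
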