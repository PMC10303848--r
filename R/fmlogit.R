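#' Fractional multinomial logit for membership probabilities
#'
#' Quasi-maximum-likelihood regression of N simplex-valued outcome rows
#' (e.g. posterior trajectory-group membership probabilities) on baseline
#' covariates. The mean is the multinomial-logit function
#' \code{mu_ig = exp(x_i' g_g) / sum_h exp(x_i' g_h)} with the reference
#' group's coefficients fixed at zero, and the quasi-log-likelihood is
#' \code{sum_i sum_g s_ig log mu_ig} — the multinomial log-likelihood
#' evaluated at fractional outcomes. For fixed data this objective is
#' concave in the coefficients; it is maximized by Newton iterations with
#' step halving from a zero start, declaring convergence when the gradient
#' norm falls below \code{tol}.
#'
#' @param shares N x G matrix; each row must sum to 1 within 1e-8 with
#'   entries in [0, 1].
#' @param design N x P numeric design matrix including an intercept column.
#'   Must be full rank; collinear or zero-variance columns raise an error
#'   naming them.
#' @param ref_group index of the reference group (coefficients fixed at 0).
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return object of class \code{"adtraj_fmlogit"}: \code{coef}
#'   ((G-1) x P matrix for the non-reference groups, rownames
#'   \code{group<g>}), \code{vcov_robust} (sandwich covariance of the
#'   stacked coefficients), \code{vcov_model} (inverse negative Hessian),
#'   \code{qll}, \code{fitted} (N x G means), convergence info, and the
#'   inputs needed for [aor_table()].
#' @export
fit_fmlogit <- function(shares, design, ref_group = 1L, tol = 1e-6,
                        max_iter = 100L) {
  shares <- as.matrix(shares)
  design <- as.matrix(design)
  N <- nrow(shares); G <- ncol(shares); P <- ncol(design)
  stopifnot(nrow(design) == N, G >= 2L)
  if (any(shares < -1e-12) || any(shares > 1 + 1e-12)) {
    stop("share entries must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(shares) - 1) > 1e-8)) {
    stop("share rows must sum to 1 within 1e-8", call. = FALSE)
  }
  if (is.null(colnames(design))) colnames(design) <- paste0("x", seq_len(P))
  sds <- apply(design, 2L, stats::sd)
  const <- which(sds == 0)
  if (length(const) > 1L || (length(const) == 1L && any(design[, const] != 1))) {
    bad <- const[apply(design[, const, drop = FALSE], 2L,
                       function(v) any(v != 1))]
    if (length(bad)) {
      stop(sprintf("zero-variance covariate column(s): %s",
                   paste(colnames(design)[bad], collapse = ", ")), call. = FALSE)
    }
  }
  qrd <- qr(design)
  if (qrd$rank < P) {
    drop_cols <- colnames(design)[qrd$pivot[(qrd$rank + 1L):P]]
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(drop_cols, collapse = ", ")), call. = FALSE)
  }

  other <- setdiff(seq_len(G), ref_group)
  K <- length(other)          # non-reference groups
  gamma <- matrix(0, K, P)    # stacked row-wise: group block then covariate

  mu_fun <- function(gamma) {
    eta <- matrix(0, N, G)
    eta[, other] <- design %*% t(gamma)
    mu <- exp(eta - .row_logsumexp(eta))
    mu / rowSums(mu)
  }
  qll_fun <- function(mu) sum(shares * log(pmax(mu, 1e-300)))

  mu <- mu_fun(gamma)
  qll <- qll_fun(mu)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    R <- shares[, other, drop = FALSE] - mu[, other, drop = FALSE]
    grad <- as.vector(crossprod(design, R))       # (K*P), covariate fastest
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    H <- matrix(0, K * P, K * P)
    for (a in seq_len(K)) for (b in a:K) {
      w <- if (a == b) mu[, other[a]] * (1 - mu[, other[a]])
           else -mu[, other[a]] * mu[, other[b]]
      blk <- crossprod(design, design * w)
      ia <- (a - 1L) * P + seq_len(P); ib <- (b - 1L) * P + seq_len(P)
      H[ia, ib] <- blk
      H[ib, ia] <- t(blk)
    }
    step <- tryCatch(solve(H, grad), error = function(e) {
      stop("singular quasi-likelihood Hessian", call. = FALSE)
    })
    lam <- 1
    repeat {
      gn <- gamma + lam * matrix(step, K, P, byrow = TRUE)
      mun <- mu_fun(gn)
      qn <- qll_fun(mun)
      if (qn >= qll - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    gamma <- gn; mu <- mun; qll <- qn
  }

  rownames(gamma) <- paste0("group", other)
  colnames(gamma) <- colnames(design)
  fit <- structure(list(
    coef = gamma, ref_group = ref_group, groups = other,
    qll = qll, fitted = mu, design = design, shares = shares,
    converged = converged, iterations = iter,
    vcov_model = NULL, vcov_robust = NULL
  ), class = "adtraj_fmlogit")
  fit$vcov_model <- .fmlogit_bread(fit)
  fit$vcov_robust <- robust_vcov(fit)
  fit
}

# inverse of the negative quasi-likelihood Hessian at the optimum
.fmlogit_bread <- function(fit) {
  design <- fit$design; mu <- fit$fitted; other <- fit$groups
  K <- length(other); P <- ncol(design)
  H <- matrix(0, K * P, K * P)
  for (a in seq_len(K)) for (b in a:K) {
    w <- if (a == b) mu[, other[a]] * (1 - mu[, other[a]])
         else -mu[, other[a]] * mu[, other[b]]
    blk <- crossprod(design, design * w)
    ia <- (a - 1L) * P + seq_len(P); ib <- (b - 1L) * P + seq_len(P)
    H[ia, ib] <- blk
    H[ib, ia] <- t(blk)
  }
  nm <- as.vector(t(outer(paste0("group", other), colnames(design),
                          paste, sep = ":")))
  dimnames(H) <- list(nm, nm)
  solve(H)
}

#' Heteroskedasticity-robust (sandwich) covariance
#'
#' \code{A^{-1} B A^{-1}} with A the negative quasi-likelihood Hessian and
#' B the sum of per-patient score outer products, robust to arbitrary
#' heteroskedasticity of the fractional outcomes.
#'
#' @param fit a converged [fit_fmlogit()] object.
#' @return covariance matrix of the stacked non-reference coefficients
#'   (ordering: group block, covariate within block).
#' @export
robust_vcov <- function(fit) {
  stopifnot(inherits(fit, "adtraj_fmlogit"))
  A_inv <- if (!is.null(fit$vcov_model)) fit$vcov_model else .fmlogit_bread(fit)
  other <- fit$groups
  R <- fit$shares[, other, drop = FALSE] - fit$fitted[, other, drop = FALSE]
  # per-patient score: kron over groups, covariate fastest within block
  U <- do.call(cbind, lapply(seq_along(other), function(a) {
    fit$design * R[, a]
  }))
  B <- crossprod(U)
  V <- A_inv %*% B %*% A_inv
  dimnames(V) <- dimnames(A_inv)
  V
}

#' Adjusted odds ratio table
#'
#' Exponentiated coefficients with Wald confidence intervals and two-sided
#' p-values from the robust standard errors, one row per non-reference
#' group x covariate.
#'
#' @param fit a [fit_fmlogit()] result.
#' @param level confidence level.
#' @param use_robust use the sandwich covariance (default) or the
#'   model-based one.
#' @return data.frame (group, covariate, coef, se, aor, ci_low, ci_high, p).
#' @export
aor_table <- function(fit, level = 0.95, use_robust = TRUE) {
  stopifnot(inherits(fit, "adtraj_fmlogit"))
  V <- if (use_robust) fit$vcov_robust else fit$vcov_model
  se <- sqrt(diag(V))
  P <- ncol(fit$design)
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (a in seq_along(fit$groups)) {
    idx <- (a - 1L) * P + seq_len(P)
    g <- fit$coef[a, ]
    s <- se[idx]
    rows[[a]] <- data.frame(
      group = fit$groups[a],
      covariate = colnames(fit$design),
      coef = as.numeric(g),
      se = as.numeric(s),
      aor = exp(as.numeric(g)),
      ci_low = exp(as.numeric(g) - z * s),
      ci_high = exp(as.numeric(g) + z * s),
      p = 2 * stats::pnorm(-abs(as.numeric(g) / s))
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a membership-regression design matrix from a covariate table
#'
#' Numeric columns enter untransformed; factors/characters are expanded to
#' treatment-coded dummies; a column with missing values gains a
#' missing-indicator companion (values imputed to 0 where missing), the
#' convention used for deprivation-index missingness.
#'
#' @param covariates data.frame.
#' @param vars covariate names to include.
#' @return numeric matrix with leading intercept column.
#' @export
membership_design <- function(covariates, vars) {
  .require_columns(covariates, vars, "covariates")
  cols <- list(`(Intercept)` = rep(1, nrow(covariates)))
  for (v in vars) {
    x <- covariates[[v]]
    if (is.character(x)) x <- factor(x)
    if (is.factor(x)) {
      for (lv in levels(x)[-1]) {
        cols[[paste0(v, lv)]] <- as.numeric(x == lv)
      }
    } else {
      x <- as.numeric(x)
      if (anyNA(x)) {
        cols[[paste0(v, "_missing")]] <- as.numeric(is.na(x))
        x[is.na(x)] <- 0
      }
      cols[[v]] <- x
    }
  }
  do.call(cbind, cols)
}

#' @export
print.adtraj_fmlogit <- function(x, ...) {
  cat(sprintf("Fractional multinomial logit: %d obs, %d groups (ref %d), %d covariates\n",
              nrow(x$shares), ncol(x$shares), x$ref_group, ncol(x$design)))
  cat(sprintf("  quasi-logL = %.4f, %s in %d iteration(s)\n", x$qll,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}
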