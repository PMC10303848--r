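#' Stage-1 specification grid search
#'
#' Fits every combination of group count (1..max_groups) and common
#' polynomial order (0..max_order) — 30 specifications at the defaults —
#' and picks the converged fit with the best (largest) BIC. Non-converged
#' cells are logged and excluded from the ranking.
#'
#' @param panel N x T 0/1 adherence matrix.
#' @param max_groups largest group count considered.
#' @param max_order largest common polynomial order considered.
#' @param starts,seed,tol,max_iter,n_convention passed to [fit_gbtm()]
#'   (standard errors are skipped during the grid for speed).
#' @param refit_winner refit the winning cell with standard errors so it
#'   can seed [reduce_orders()].
#' @return object of class \code{"adtraj_selection"}: \code{grid}
#'   (data.frame G, order, loglik, k, bic, converged), \code{winner_spec},
#'   \code{winner_fit} (when \code{refit_winner}), and an empty reduction
#'   trace.
#' @export
grid_search <- function(panel, max_groups = 5L, max_order = 5L,
                        starts = 10L, seed = 1L, tol = 1e-7,
                        max_iter = 500L, n_convention = "patients",
                        refit_winner = TRUE) {
  panel <- .assert_binary_panel(panel)
  cells <- expand.grid(G = seq_len(max_groups), order = 0:max_order)
  grid <- data.frame(G = cells$G, order = cells$order, loglik = NA_real_,
                     k = NA_integer_, bic = NA_real_, converged = FALSE)
  fits <- vector("list", nrow(cells))
  for (j in seq_len(nrow(cells))) {
    spec <- trajectory_spec(cells$G[j], cells$order[j])
    fit <- fit_gbtm(panel, spec, starts = starts, seed = seed + j, tol = tol,
                    max_iter = max_iter, se = FALSE,
                    n_convention = n_convention)
    fits[[j]] <- fit
    grid$loglik[j] <- fit$loglik
    grid$k[j] <- fit$k
    grid$bic[j] <- fit$bic
    grid$converged[j] <- fit$convergence$converged
  }
  ok <- which(grid$converged)
  if (!length(ok)) stop("no grid specification converged", call. = FALSE)
  # best BIC among converged cells; ties broken by fewer parameters
  ord <- ok[order(-grid$bic[ok], grid$k[ok])]
  win <- ord[1]
  winner_spec <- trajectory_spec(grid$G[win], grid$order[win])
  winner_fit <- if (refit_winner) {
    add_gbtm_se(fits[[win]], panel)
  } else fits[[win]]
  structure(list(grid = grid, winner_index = win, winner_spec = winner_spec,
                 winner_fit = winner_fit,
                 reduction_trace = data.frame(step = integer(0),
                                              group = integer(0),
                                              p_value = numeric(0),
                                              orders = character(0)),
                 final_fit = winner_fit,
                 min_share_ok = NA, seed = seed),
            class = "adtraj_selection")
}

#' Stage-2 per-group polynomial order reduction
#'
#' Starting from the stage-1 winner, repeatedly: test each group's
#' highest-order coefficient (Wald, normal reference); if any group's
#' highest term has p >= alpha, reduce the order of the worst offender
#' (largest p) by one and refit — one change per refit, which makes the
#' search deterministic. Stops when every group's highest retained term is
#' significant or sits at the order-0 floor (an order-0 group is never
#' reduced further even when its intercept is non-significant). Afterwards
#' the smallest assigned group share is checked against \code{min_share};
#' on violation the search is re-run at G - 1 groups (stage-1 common
#' order) and the result flagged.
#'
#' @param panel 0/1 adherence matrix.
#' @param selection result of [grid_search()] (or a list with
#'   \code{winner_fit}).
#' @param alpha significance level for the highest-term Wald tests.
#' @param min_share minimum acceptable smallest assigned group share.
#' @param starts,seed,tol,max_iter passed to [fit_gbtm()] for refits.
#' @return the selection object with \code{reduction_trace},
#'   \code{final_fit}, \code{final_spec}, \code{min_share_ok} and
#'   \code{floor_groups} (groups stuck at order 0 with a non-significant
#'   intercept) filled in.
#' @export
reduce_orders <- function(panel, selection, alpha = 0.05, min_share = 0.05,
                          starts = 10L, seed = 1L, tol = 1e-7,
                          max_iter = 500L) {
  panel <- .assert_binary_panel(panel)
  fit <- selection$winner_fit
  if (is.null(fit$se)) fit <- add_gbtm_se(fit, panel)
  trace <- list()
  step <- 0L
  repeat {
    wt <- wald_highest_terms(fit)
    reducible <- wt$p >= alpha & fit$spec$orders > 0L
    if (!any(reducible)) break
    g <- which(reducible)[which.max(wt$p[reducible])]
    step <- step + 1L
    new_orders <- fit$spec$orders
    new_orders[g] <- new_orders[g] - 1L
    trace[[step]] <- data.frame(step = step, group = g, p_value = wt$p[g],
                                orders = paste(new_orders, collapse = ","))
    fit <- fit_gbtm(panel, trajectory_spec(fit$spec$G, new_orders),
                    starts = starts, seed = seed + 1000L + step, tol = tol,
                    max_iter = max_iter, se = TRUE)
  }
  wt <- wald_highest_terms(fit)
  floor_groups <- which(fit$spec$orders == 0L & wt$p >= alpha)

  share <- tabulate(fit$labels, fit$spec$G) / fit$n
  min_share_ok <- min(share) >= min_share
  fellback <- FALSE
  if (!min_share_ok && fit$spec$G > 1L) {
    # documented fallback: the published rule states the constraint but not
    # the remedy; drop one group at the stage-1 common order and re-reduce
    fellback <- TRUE
    common_order <- max(selection$winner_spec$orders)
    sub <- selection
    sub$winner_spec <- trajectory_spec(fit$spec$G - 1L, common_order)
    sub$winner_fit <- fit_gbtm(panel, sub$winner_spec, starts = starts,
                               seed = seed + 5000L, tol = tol,
                               max_iter = max_iter, se = TRUE)
    sub <- reduce_orders(panel, sub, alpha, min_share, starts,
                         seed + 5000L, tol, max_iter)
    fit <- sub$final_fit
    trace <- c(trace, list(sub$reduction_trace))
    floor_groups <- sub$floor_groups
    share <- tabulate(fit$labels, fit$spec$G) / fit$n
    min_share_ok <- min(share) >= min_share
  }
  selection$reduction_trace <- if (length(trace)) {
    do.call(rbind, trace)
  } else selection$reduction_trace
  selection$final_fit <- fit
  selection$final_spec <- fit$spec
  selection$floor_groups <- floor_groups
  selection$min_share_ok <- min_share_ok
  selection$min_share_fallback <- fellback
  selection
}

#' Two-stage model selection
#'
#' Convenience wrapper: [grid_search()] then [reduce_orders()].
#'
#' @inheritParams grid_search
#' @inheritParams reduce_orders
#' @return an \code{"adtraj_selection"} with the final fit.
#' @export
select_model <- function(panel, max_groups = 5L, max_order = 5L,
                         alpha = 0.05, min_share = 0.05, starts = 10L,
                         seed = 1L, tol = 1e-7, max_iter = 500L,
                         n_convention = "patients") {
  sel <- grid_search(panel, max_groups, max_order, starts, seed, tol,
                     max_iter, n_convention)
  reduce_orders(panel, sel, alpha, min_share, starts, seed, tol, max_iter)
}

#' @export
print.adtraj_selection <- function(x, ...) {
  cat(sprintf("Specification search over %d candidate models\n", nrow(x$grid)))
  w <- x$winner_spec
  cat(sprintf("  stage-1 winner: G = %d, common order %d\n", w$G, w$orders[1]))
  if (nrow(x$reduction_trace)) {
    cat(sprintf("  %d order-reduction step(s); final orders (%s)\n",
                nrow(x$reduction_trace),
                paste(x$final_fit$spec$orders, collapse = ", ")))
  } else {
    cat("  no order reduction applied\n")
  }
  if (!is.na(x$min_share_ok)) {
    cat(sprintf("  min assigned share constraint satisfied: %s\n",
                x$min_share_ok))
  }
  invisible(x)
}
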