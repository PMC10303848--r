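#' Assign patients to their most likely trajectory group
#'
#' Argmax of each posterior row; exact ties go to the lowest group index
#' and are flagged.
#'
#' @param posteriors N x G matrix with rows summing to 1.
#' @return list with \code{labels} (integer vector) and \code{ties}
#'   (logical vector marking rows whose maximum was not unique).
#' @export
assign_groups <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  labels <- max.col(posteriors, ties.method = "first")
  mx <- posteriors[cbind(seq_len(nrow(posteriors)), labels)]
  ties <- rowSums(abs(posteriors - mx) < 1e-12) > 1L
  list(labels = labels, ties = ties)
}

#' Average posterior probability of assignment (APP)
#'
#' \code{APP_g} is the mean posterior membership probability of group g
#' among the patients assigned to g. Groups with no assigned members get
#' NA and a flag.
#'
#' @param posteriors N x G posterior matrix.
#' @param labels assigned group labels (defaults to the argmax assignment).
#' @return named numeric vector of length G with attribute
#'   \code{"empty_groups"}.
#' @export
app <- function(posteriors, labels = NULL) {
  posteriors <- as.matrix(posteriors)
  G <- ncol(posteriors)
  if (is.null(labels)) labels <- assign_groups(posteriors)$labels
  out <- vapply(seq_len(G), function(g) {
    members <- labels == g
    if (!any(members)) return(NA_real_)
    mean(posteriors[members, g])
  }, numeric(1))
  names(out) <- paste0("group", seq_len(G))
  attr(out, "empty_groups") <- unname(which(is.na(out)))
  out
}

#' Odds of correct classification (OCC)
#'
#' \code{OCC_g = [APP_g / (1 - APP_g)] / [pi_g / (1 - pi_g)]}: the odds of
#' membership under assignment relative to the odds implied by the
#' estimated mixing probability alone. APP or pi at a boundary returns a
#' capped value with a flag.
#'
#' @param app_g per-group APP values.
#' @param pi_g per-group mixing probabilities (the model's estimated pi by
#'   convention; assigned shares are a user-supplied alternative).
#' @return numeric vector with attribute \code{"capped"}.
#' @export
occ <- function(app_g, pi_g) {
  stopifnot(length(app_g) == length(pi_g))
  capped <- app_g >= 1 | app_g <= 0 | pi_g >= 1 | pi_g <= 0
  a <- pmin(pmax(app_g, 1e-12), 1 - 1e-12)
  p <- pmin(pmax(pi_g, 1e-12), 1 - 1e-12)
  out <- (a / (1 - a)) / (p / (1 - p))
  attr(out, "capped") <- which(capped & !is.na(app_g))
  out
}

#' Relative entropy of a posterior classification
#'
#' \code{E = 1 - sum_i sum_g (-p_ig log p_ig) / (N log G)}, with
#' \code{0 log 0 = 0}. One is certain classification, zero is maximal
#' confusion. A single-group model returns 1 by convention (flagged).
#'
#' @param posteriors N x G posterior matrix.
#' @return scalar in [0, 1].
#' @export
relative_entropy <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  G <- ncol(posteriors)
  if (G == 1L) {
    out <- 1
    attr(out, "single_group") <- TRUE
    return(out)
  }
  p <- posteriors
  h <- -p * log(p)
  h[p == 0] <- 0
  1 - sum(h) / (nrow(p) * log(G))
}

#' Observed and fitted trajectories per group
#'
#' For each assigned group: the mean observed adherence by month among its
#' members and the fitted inverse-logit trajectory; plus per-patient
#' adherence sequences tagged by assigned group for spaghetti-plot export.
#'
#' @param panel N x T 0/1 panel.
#' @param posteriors posterior matrix.
#' @param params fitted [gbtm_params()].
#' @return list with \code{summary} (group, month, observed, fitted,
#'   n_members; empty groups appear with NA observed and a flag) and
#'   \code{spaghetti} (patient, group, month, adherent).
#' @export
trajectory_tables <- function(panel, posteriors, params) {
  panel <- .assert_binary_panel(panel)
  Tm <- ncol(panel)
  G <- length(params$pi)
  labels <- assign_groups(posteriors)$labels
  fitted <- .traj_probs(params$beta, Tm)
  rows <- lapply(seq_len(G), function(g) {
    members <- labels == g
    data.frame(group = g, month = seq_len(Tm),
               observed = if (any(members)) {
                 colMeans(panel[members, , drop = FALSE])
               } else NA_real_,
               fitted = fitted[, g],
               n_members = sum(members))
  })
  spaghetti <- data.frame(
    patient = rep(seq_len(nrow(panel)), each = Tm),
    group = rep(labels, each = Tm),
    month = rep(seq_len(Tm), nrow(panel)),
    adherent = as.integer(t(panel))
  )
  list(summary = do.call(rbind, rows), spaghetti = spaghetti,
       empty_groups = which(tabulate(labels, G) == 0L))
}

#' Full model-adequacy report
#'
#' Computes APP, OCC, relative entropy, estimated and assigned group
#' shares, and the published adequacy flags (APP >= 0.7 per group,
#' OCC > 5 per group, relative entropy >= 0.7).
#'
#' @param fit fitted \code{"adtraj_gbtm"}.
#' @param panel the panel the model was fit to.
#' @param pi_source "estimated" uses the model's mixing probabilities in
#'   OCC (standard); "assigned" uses assigned shares.
#' @return object of class \code{"adtraj_diagnostics"}.
#' @export
model_diagnostics <- function(fit, panel,
                              pi_source = c("estimated", "assigned")) {
  stopifnot(inherits(fit, "adtraj_gbtm"))
  pi_source <- match.arg(pi_source)
  post <- fit$posteriors
  G <- fit$spec$G
  labels <- assign_groups(post)$labels
  app_g <- app(post, labels)
  assigned_share <- tabulate(labels, G) / length(labels)
  pi_used <- if (pi_source == "estimated") fit$params$pi else assigned_share
  occ_g <- occ(app_g, pi_used)
  ent <- relative_entropy(post)
  traj <- trajectory_tables(panel, post, fit$params)
  structure(list(
    app = app_g,
    occ = occ_g,
    pi = fit$params$pi,
    assigned_share = assigned_share,
    relative_entropy = as.numeric(ent),
    pass = c(app = all(app_g >= 0.7, na.rm = TRUE),
             occ = all(occ_g > 5, na.rm = TRUE),
             entropy = as.numeric(ent) >= 0.7),
    trajectories = traj$summary,
    spaghetti = traj$spaghetti,
    empty_groups = traj$empty_groups
  ), class = "adtraj_diagnostics")
}

#' @export
print.adtraj_diagnostics <- function(x, ...) {
  cat("Trajectory model adequacy:\n")
  tab <- data.frame(group = seq_along(x$app),
                    pi = round(x$pi, 4),
                    assigned = round(x$assigned_share, 4),
                    APP = round(as.numeric(x$app), 4),
                    OCC = round(as.numeric(x$occ), 2))
  print(tab, row.names = FALSE)
  cat(sprintf("Relative entropy: %.4f\n", x$relative_entropy))
  cat(sprintf("Pass flags: APP>=0.7 %s | OCC>5 %s | entropy>=0.7 %s\n",
              x$pass["app"], x$pass["occ"], x$pass["entropy"]))
  invisible(x)
}
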