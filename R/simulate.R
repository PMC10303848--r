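#' Simulate covariates, latent group labels and an adherence panel
#'
#' Draws each patient's trajectory group from the scenario's mixture (or
#' from a covariate-driven multinomial logit when \code{membership_coefs}
#' is supplied), then draws the monthly binary adherence indicators
#' independently across months with probability equal to the inverse logit
#' of the group's polynomial at that month. An optional Markov-persistence
#' knob introduces within-group serial dependence for robustness checks;
#' the default (0) matches the conditional-independence assumption of the
#' trajectory model.
#'
#' @param scn a [scenario()].
#' @return an object of class \code{"adtraj_cohort"}: a list with
#'   \code{covariates} (data.frame, or NULL when the scenario has no
#'   covariate spec), \code{labels} (integer vector of true groups),
#'   \code{panel} (n_patients x n_months 0/1 matrix with patient ids as
#'   rownames), and the generating \code{scenario}.
#' @export
simulate_panel <- function(scn) {
  stopifnot(inherits(scn, "adtraj_scenario"))
  set.seed(scn$seed)
  n <- scn$n_patients
  G <- length(scn$group_probs)
  covariates <- if (!is.null(scn$covariate_spec)) {
    .simulate_covariates(scn$covariate_spec, n)
  } else NULL

  if (!is.null(scn$membership_coefs)) {
    if (is.null(covariates)) {
      stop("membership_coefs requires a covariate_spec", call. = FALSE)
    }
    vars <- colnames(scn$membership_coefs)
    .require_columns(covariates, vars, "covariates")
    X <- as.matrix(covariates[, vars, drop = FALSE])
    if (anyNA(X)) X[is.na(X)] <- 0  # membership model ignores missing values
    # reference group 1 has linear predictor 0; intercepts come from the
    # mixture's log-odds so that effects perturb the stated shares
    eta <- cbind(0, matrix(log(scn$group_probs[-1] / scn$group_probs[1]),
                           n, G - 1L, byrow = TRUE) +
                   X %*% t(scn$membership_coefs))
    pr <- exp(eta - .row_logsumexp(eta))
    labels <- vapply(seq_len(n), function(i) {
      sample.int(G, 1L, prob = pr[i, ])
    }, integer(1))
  } else {
    labels <- sample.int(G, n, replace = TRUE, prob = scn$group_probs)
  }

  pmat <- scenario_trajectory_probs(scn)        # n_months x G
  probs <- t(pmat[, labels, drop = FALSE])      # n x n_months
  panel <- matrix(stats::rbinom(n * scn$n_months, 1L, probs),
                  nrow = n, ncol = scn$n_months)
  if (scn$markov_persistence > 0) {
    for (m in 2:scn$n_months) {
      copy <- stats::runif(n) < scn$markov_persistence
      panel[copy, m] <- panel[copy, m - 1L]
    }
  }
  rownames(panel) <- seq_len(n)
  colnames(panel) <- paste0("m", seq_len(scn$n_months))
  structure(list(covariates = covariates, labels = labels, panel = panel,
                 scenario = scn),
            class = "adtraj_cohort")
}

.simulate_covariates <- function(spec, n) {
  out <- data.frame(patient_id = seq_len(n))
  for (nm in names(spec)) {
    s <- spec[[nm]]
    x <- switch(s$dist,
      normal = stats::rnorm(n, s$mean, s$sd),
      bernoulli = stats::rbinom(n, 1L, s$p),
      categorical = {
        lv <- unlist(s$levels)
        factor(sample(lv, n, replace = TRUE, prob = unlist(s$probs)), levels = lv)
      },
      poisson = stats::rpois(n, s$lambda),
      gamma = stats::rgamma(n, shape = s$shape, scale = s$scale),
      stop(sprintf("unknown covariate distribution '%s' for '%s'", s$dist, nm),
           call. = FALSE)
    )
    if (is.numeric(x)) {
      if (!is.null(s$min)) x <- pmax(x, s$min)
      if (!is.null(s$max)) x <- pmin(x, s$max)
      if (isTRUE(s$round)) x <- round(x)
    }
    if (!is.null(s$prop_missing) && s$prop_missing > 0) {
      x[stats::runif(n) < s$prop_missing] <- NA
    }
    out[[nm]] <- x
  }
  out
}

#' Generate claims-shaped tables consistent with an adherence panel
#'
#' Emits fill, enrollment, and diagnosis tables for a simulated cohort.
#' Every patient receives an index fill of 30 days' supply at day 0 (the
#' index prescription defines day 0, so the first 30-day month is covered
#' by construction). Each subsequent adherent month receives a 30-day fill
#' at that month's start; a non-adherent month receives either no fill or,
#' with probability \code{short_fill_prob} from the scenario, a short fill
#' of 1-23 days (too short to cross the 80 percent PDC threshold).
#' Enrollment spans the full baseline + follow-up window and each patient
#' carries two qualifying outpatient IPF diagnosis claims in baseline.
#'
#' @param scn the generating [scenario()].
#' @param cohort output of [simulate_panel()].
#' @return the cohort with added \code{fills}, \code{enrollment} and
#'   \code{diagnoses} data.frames. Days are integer offsets from the index
#'   date (day 0); baseline is [-360, -1], follow-up [0, 359] for the
#'   default 12 months.
#' @export
simulate_claims <- function(scn, cohort) {
  stopifnot(inherits(scn, "adtraj_scenario"), inherits(cohort, "adtraj_cohort"))
  set.seed(scn$seed + 1L)
  n <- scn$n_patients
  panel <- cohort$panel
  horizon <- 30L * scn$n_months

  fills <- vector("list", n)
  for (i in seq_len(n)) {
    days <- 0L                      # index fill, always >= 30 days' supply
    supply <- 30L
    for (m in 2:scn$n_months) {
      start <- 30L * (m - 1L)
      if (panel[i, m] == 1L) {
        days <- c(days, start); supply <- c(supply, 30L)
      } else if (scn$short_fill_prob > 0 &&
                 stats::runif(1) < scn$short_fill_prob) {
        days <- c(days, start)
        supply <- c(supply, sample.int(23L, 1L))
      }
    }
    fills[[i]] <- data.frame(patient_id = i, drug = "nintedanib",
                             day = days, days_supply = supply)
  }
  fills <- do.call(rbind, fills)

  enrollment <- data.frame(
    patient_id = seq_len(n),
    start_day = -horizon,
    end_day = horizon - 1L,
    dual_eligible = 0L
  )
  diagnoses <- data.frame(
    patient_id = rep(seq_len(n), each = 2L),
    day = rep(c(-180L, -90L), n),
    code = "IPF",
    setting = "outpatient"
  )
  if (!is.null(cohort$covariates) && !"death_day" %in% names(cohort$covariates)) {
    cohort$covariates$death_day <- NA_real_
  }
  cohort$fills <- fills
  cohort$enrollment <- enrollment
  cohort$diagnoses <- diagnoses
  cohort
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_panel()] then [simulate_claims()].
#'
#' @param scn a [scenario()].
#' @return an \code{"adtraj_cohort"} with covariates, labels, panel, fills,
#'   enrollment and diagnoses.
#' @export
simulate_cohort <- function(scn) {
  simulate_claims(scn, simulate_panel(scn))
}

#' Write cohort tables as CSV files
#'
#' @param cohort an \code{"adtraj_cohort"}.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(cohort$covariates)) wr(cohort$covariates, "covariates.csv")
  panel_df <- data.frame(patient_id = as.integer(rownames(cohort$panel)),
                         true_group = cohort$labels, cohort$panel)
  wr(panel_df, "panel.csv")
  if (!is.null(cohort$fills)) wr(cohort$fills, "fills.csv")
  if (!is.null(cohort$enrollment)) wr(cohort$enrollment, "enrollment.csv")
  if (!is.null(cohort$diagnoses)) wr(cohort$diagnoses, "diagnoses.csv")
  invisible(paths)
}

#' Ten-patient fixture exercising every cohort filter
#'
#' Builds claims-shaped tables for 10 patients: patient 1 satisfies every
#' inclusion criterion; patients 2-10 each violate exactly one filter (in
#' the order the filters are applied), so sequential filtering excludes one
#' patient per step and retains exactly one.
#'
#' @return a list of tables (\code{covariates}, \code{fills},
#'   \code{enrollment}, \code{diagnoses}) suitable for [apply_filters()].
#' @export
make_filter_fixture <- function() {
  n <- 10L
  covariates <- data.frame(
    patient_id = 1:10,
    age = c(75, 65, rep(75, 8)),       # patient 2: under 66 at index
    death_day = c(rep(NA_real_, 9), 300)  # patient 10: dies during follow-up
  )
  enrollment <- data.frame(
    patient_id = 1:10,
    start_day = rep(-360L, 10),
    end_day = c(359L, 359L, 200L, rep(359L, 7)),  # patient 3: coverage gap
    dual_eligible = c(rep(0L, 6), 1L, rep(0L, 3)) # patient 7: dual eligible
  )
  # patient 4: two outpatient IPF claims only 10 days apart, no inpatient
  diagnoses <- rbind(
    data.frame(patient_id = rep(setdiff(1:10, c(4L, 8L)), each = 2L),
               day = rep(c(-180L, -90L), 8L),
               code = "IPF", setting = "outpatient"),
    data.frame(patient_id = c(4L, 4L), day = c(-100L, -90L),
               code = "IPF", setting = "outpatient"),
    data.frame(patient_id = c(8L, 8L), day = c(-180L, -90L),
               code = "IPF", setting = "outpatient"),
    # patient 6: skilled-nursing-facility use during follow-up
    data.frame(patient_id = 6L, day = 50L, code = "SNF", setting = "inpatient"),
    # patient 8: baseline lung-cancer diagnosis
    data.frame(patient_id = 8L, day = -50L, code = "LUNG_CANCER",
               setting = "outpatient")
  )
  fills <- rbind(
    data.frame(patient_id = 1:10, drug = "nintedanib", day = 0L,
               days_supply = 30L),
    # patient 5: antifibrotic use during baseline
    data.frame(patient_id = 5L, drug = "pirfenidone", day = -100L,
               days_supply = 30L),
    # patient 9: pirfenidone overlapping nintedanib supply in follow-up
    data.frame(patient_id = 9L, drug = "pirfenidone", day = 10L,
               days_supply = 30L)
  )
  list(covariates = covariates, fills = fills, enrollment = enrollment,
       diagnoses = diagnoses)
}
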