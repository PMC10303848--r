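#' Identify each patient's index day
#'
#' The index date is the day of the first qualifying fill of the index
#' drug; patients with no qualifying fill are dropped. Ties (two fills on
#' the same day) are a no-op since the minimum is unique by value.
#'
#' @param fills data.frame with \code{patient_id}, \code{day}, and
#'   optionally \code{drug}.
#' @param drug_name index drug label.
#' @return data.frame (patient_id, index_day), one row per patient with at
#'   least one qualifying fill; empty input yields an empty result.
#' @export
identify_index <- function(fills, drug_name = "nintedanib") {
  .require_columns(fills, c("patient_id", "day"), "fills")
  if ("drug" %in% names(fills)) fills <- fills[fills$drug == drug_name, ]
  if (nrow(fills) == 0L) {
    return(data.frame(patient_id = integer(0), index_day = integer(0)))
  }
  agg <- stats::aggregate(day ~ patient_id, data = fills, FUN = min)
  names(agg)[2] <- "index_day"
  agg[order(agg$patient_id), , drop = FALSE]
}

# Default windows (days relative to index): baseline [-360, -1],
# follow-up [0, 359]; a single 30-day-month time base for both adherence
# and eligibility avoids mixing day conventions.
.default_cohort_config <- function() {
  list(baseline = c(-360L, -1L), followup = c(0L, 359L),
       min_age = 66, dx_gap_days = 14L,
       index_drug = "nintedanib",
       antifibrotics = c("nintedanib", "pirfenidone"),
       institutional_codes = c("LUNG_TRANSPLANT", "SNF", "LTC", "HOSPICE"),
       exclusionary_dx = c("LUNG_CANCER", "AUTOIMMUNE"))
}

#' Apply the cohort inclusion/exclusion filters
#'
#' Applies, in order, the claims-based sample-selection rules and returns
#' an attrition table (one row per filter) plus the retained patient set.
#' The filters, all relative to the index day (day 0):
#' \enumerate{
#'   \item age at index >= 66;
#'   \item continuous enrollment over baseline + follow-up
#'     (spells covering every day of [-360, 359]);
#'   \item qualifying diagnosis in baseline: at least one inpatient IPF
#'     claim, or two outpatient IPF claims at least 14 days apart
#'     (inclusive: exactly 14 days qualifies);
#'   \item no antifibrotic fill during baseline;
#'   \item no lung transplant / skilled nursing / long-term care / hospice
#'     claim during baseline or follow-up;
#'   \item no dual Medicare-Medicaid eligibility during baseline or
#'     follow-up;
#'   \item no baseline lung-cancer or autoimmune diagnosis;
#'   \item no pirfenidone supply overlapping the index drug's supply during
#'     follow-up;
#'   \item alive through the end of follow-up.
#' }
#' The filters are conjunctive predicates, so reordering changes the
#' per-step counts but never the final set.
#'
#' @param tables list with data.frames \code{covariates} (patient_id, age,
#'   death_day), \code{fills}, \code{enrollment} (patient_id, start_day,
#'   end_day, dual_eligible) and \code{diagnoses} (patient_id, day, code,
#'   setting).
#' @param config optional list overriding the default windows/labels;
#'   \code{filter_order} (a permutation of the filter names) reorders the
#'   attrition steps without changing the final set.
#' @return object of class \code{"adtraj_filter_result"}: list with
#'   \code{attrition} (filter, n_before, n_excluded, n_after) and
#'   \code{patient_ids} (retained ids).
#' @export
apply_filters <- function(tables, config = list()) {
  cfg <- utils::modifyList(.default_cohort_config(), config)
  .require_columns(tables$covariates, c("patient_id", "age"), "covariates")
  .require_columns(tables$fills, c("patient_id", "drug", "day", "days_supply"),
                   "fills")
  .require_columns(tables$enrollment,
                   c("patient_id", "start_day", "end_day", "dual_eligible"),
                   "enrollment")
  .require_columns(tables$diagnoses, c("patient_id", "day", "code", "setting"),
                   "diagnoses")

  idx <- identify_index(tables$fills, cfg$index_drug)
  ids <- idx$patient_id
  cov <- tables$covariates
  bl <- cfg$baseline; fu <- cfg$followup

  preds <- list(
    age_66_plus = function(id) {
      cov$age[match(id, cov$patient_id)] >= cfg$min_age
    },
    continuous_enrollment = function(id) {
      sp <- tables$enrollment[tables$enrollment$patient_id == id, ]
      if (nrow(sp) == 0L) return(FALSE)
      need <- bl[1]:fu[2]
      covered <- unlist(mapply(seq, sp$start_day, sp$end_day, SIMPLIFY = FALSE))
      all(need %in% covered)
    },
    ipf_diagnosis = function(id) {
      dx <- tables$diagnoses
      dx <- dx[dx$patient_id == id & dx$code == "IPF" &
                 dx$day >= bl[1] & dx$day <= bl[2], ]
      if (any(dx$setting == "inpatient")) return(TRUE)
      out_days <- sort(dx$day[dx$setting == "outpatient"])
      length(out_days) >= 2L &&
        (max(out_days) - min(out_days)) >= cfg$dx_gap_days
    },
    no_baseline_antifibrotic = function(id) {
      f <- tables$fills
      !any(f$patient_id == id & f$drug %in% cfg$antifibrotics &
             f$day >= bl[1] & f$day <= bl[2])
    },
    no_institutional_care = function(id) {
      dx <- tables$diagnoses
      !any(dx$patient_id == id & dx$code %in% cfg$institutional_codes &
             dx$day >= bl[1] & dx$day <= fu[2])
    },
    no_dual_eligibility = function(id) {
      sp <- tables$enrollment
      !any(sp$patient_id == id & sp$dual_eligible == 1 &
             sp$end_day >= bl[1] & sp$start_day <= fu[2])
    },
    no_exclusionary_dx = function(id) {
      dx <- tables$diagnoses
      !any(dx$patient_id == id & dx$code %in% cfg$exclusionary_dx &
             dx$day >= bl[1] & dx$day <= bl[2])
    },
    no_pirfenidone_overlap = function(id) {
      f <- tables$fills[tables$fills$patient_id == id, ]
      pir <- f[f$drug == "pirfenidone" & f$day >= fu[1] & f$day <= fu[2], ]
      if (nrow(pir) == 0L) return(TRUE)
      nin <- f[f$drug == cfg$index_drug & f$day >= fu[1], ]
      if (nrow(nin) == 0L) return(TRUE)
      cal <- build_supply_calendar(nin$day, nin$days_supply, fu[2] + 1L)
      for (j in seq_len(nrow(pir))) {
        span <- (pir$day[j] + 1L):min(pir$day[j] + pir$days_supply[j], fu[2] + 1L)
        if (any(cal[span])) return(FALSE)
      }
      TRUE
    },
    alive_through_followup = function(id) {
      if (!"death_day" %in% names(cov)) return(TRUE)
      d <- cov$death_day[match(id, cov$patient_id)]
      is.na(d) || d > fu[2]
    }
  )

  if (!is.null(cfg$filter_order)) {
    stopifnot(setequal(cfg$filter_order, names(preds)))
    preds <- preds[cfg$filter_order]
  }
  attr_rows <- vector("list", length(preds))
  for (k in seq_along(preds)) {
    keep <- vapply(ids, preds[[k]], logical(1))
    attr_rows[[k]] <- data.frame(filter = names(preds)[k],
                                 n_before = length(ids),
                                 n_excluded = sum(!keep),
                                 n_after = sum(keep))
    ids <- ids[keep]
  }
  structure(list(attrition = do.call(rbind, attr_rows), patient_ids = ids),
            class = "adtraj_filter_result")
}

#' @export
print.adtraj_filter_result <- function(x, ...) {
  cat("Cohort attrition:\n")
  print(x$attrition, row.names = FALSE)
  cat(sprintf("Final sample: %d patients\n", length(x$patient_ids)))
  invisible(x)
}
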