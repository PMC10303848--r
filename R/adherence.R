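#' Build a daily supply calendar with stockpiling
#'
#' Converts a patient's fills into a boolean day-level coverage vector over
#' \code{[0, horizon)}. Fills are processed in ascending day order with full
#' carry-forward stockpiling (the standard PDC convention): each fill's
#' supply begins at the later of its fill day and the day the previously
#' accumulated supply runs out, then covers \code{days_supply} consecutive
#' days. Same-day fills merge additively into the queue, so their relative
#' order is irrelevant. Coverage is truncated at the horizon; stockpiled
#' supply is not capped.
#'
#' @param day integer vector of fill days (offsets from index, day 0 = index
#'   date); must be non-negative. A data.frame with columns \code{day} and
#'   \code{days_supply} may be given instead.
#' @param days_supply integer vector of days supplied per fill; must be
#'   positive.
#' @param horizon number of follow-up days (default 360 = twelve 30-day
#'   months).
#' @return logical vector of length \code{horizon}; element d+1 is TRUE when
#'   day d is covered.
#' @examples
#' cal <- build_supply_calendar(c(0, 20), c(30, 30))
#' sum(cal)  # 60: the overlapping second fill is deferred, days 0-59 covered
#' @export
build_supply_calendar <- function(day, days_supply = NULL, horizon = 360L) {
  if (is.data.frame(day)) {
    .require_columns(day, c("day", "days_supply"), "fills")
    days_supply <- day$days_supply
    day <- day$day
  }
  stopifnot(length(day) == length(days_supply))
  if (length(day) == 0L) return(rep(FALSE, horizon))
  if (any(day < 0)) stop("fill day must be non-negative", call. = FALSE)
  if (any(days_supply < 1)) stop("days_supply must be >= 1", call. = FALSE)
  o <- order(day)
  day <- as.integer(day[o]); days_supply <- as.integer(days_supply[o])
  covered <- rep(FALSE, horizon)
  ptr <- 0L  # first day not yet covered by accumulated supply
  for (j in seq_along(day)) {
    start <- max(day[j], ptr)
    end <- start + days_supply[j]   # exclusive
    if (start < horizon) covered[(start + 1L):min(end, horizon)] <- TRUE
    ptr <- end
  }
  covered
}

#' Monthly proportion of days covered
#'
#' Splits the supply calendar into consecutive 30-day months (month m covers
#' days \code{[30(m-1), 30m)}) and returns covered days / 30 per month.
#'
#' @param calendar logical coverage vector from [build_supply_calendar()].
#' @param month_days days per month (fixed 30-day months by default).
#' @return numeric vector of length \code{length(calendar) / month_days}.
#' @export
monthly_pdc <- function(calendar, month_days = 30L) {
  n_months <- length(calendar) %/% month_days
  stopifnot(n_months >= 1L)
  idx <- rep(seq_len(n_months), each = month_days)
  as.numeric(tapply(calendar[seq_len(n_months * month_days)], idx, sum)) / month_days
}

#' Dichotomize monthly PDC into adherence indicators
#'
#' @param pdc numeric vector of monthly PDC fractions in [0, 1].
#' @param threshold adherence cut point; the comparison is inclusive, so a
#'   month at exactly 0.8 counts as adherent.
#' @return integer 0/1 vector.
#' @export
dichotomize <- function(pdc, threshold = 0.8) {
  if (any(pdc < 0 | pdc > 1)) stop("PDC fractions must lie in [0, 1]", call. = FALSE)
  as.integer(pdc >= threshold)
}

#' Overall PDC over the full horizon
#'
#' @param calendar logical coverage vector.
#' @return covered days divided by horizon length.
#' @export
overall_pdc <- function(calendar) sum(calendar) / length(calendar)

#' Adherence series for every patient in a fills table
#'
#' Runs the supply-calendar / monthly-PDC / dichotomization chain per
#' patient and returns tidy and wide outputs.
#'
#' @param fills data.frame with columns \code{patient_id}, \code{day},
#'   \code{days_supply} and optionally \code{drug} (filtered to
#'   \code{drug_name} when present). Baseline fills (negative days) are
#'   ignored.
#' @param horizon follow-up days (default 360).
#' @param threshold adherence threshold on monthly PDC.
#' @param drug_name drug to measure adherence for.
#' @return list with \code{long} (patient, month, pdc, adherent),
#'   \code{panel} (patients x months 0/1 matrix), and \code{overall}
#'   (patient, overall_pdc).
#' @export
compute_adherence <- function(fills, horizon = 360L, threshold = 0.8,
                              drug_name = "nintedanib") {
  .require_columns(fills, c("patient_id", "day", "days_supply"), "fills")
  if ("drug" %in% names(fills)) fills <- fills[fills$drug == drug_name, ]
  fills <- fills[fills$day >= 0, ]
  ids <- sort(unique(fills$patient_id))
  n_months <- horizon %/% 30L
  rows <- vector("list", length(ids))
  panel <- matrix(0L, length(ids), n_months,
                  dimnames = list(ids, paste0("m", seq_len(n_months))))
  overall <- numeric(length(ids))
  for (k in seq_along(ids)) {
    f <- fills[fills$patient_id == ids[k], ]
    cal <- build_supply_calendar(f$day, f$days_supply, horizon)
    pdc <- monthly_pdc(cal)
    adh <- dichotomize(pdc, threshold)
    panel[k, ] <- adh
    overall[k] <- overall_pdc(cal)
    rows[[k]] <- data.frame(patient_id = ids[k], month = seq_len(n_months),
                            pdc = pdc, adherent = adh)
  }
  list(long = do.call(rbind, rows), panel = panel,
       overall = data.frame(patient_id = ids, overall_pdc = overall))
}
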