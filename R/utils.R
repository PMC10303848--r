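#' @keywords internal
"_PACKAGE"

# Numerically safe inverse logit / logit on a clipped linear predictor.
# Clipping bounds the mixture likelihood when a month is (near) separated,
# e.g. an all-adherent first month induced by index fills.
.clip <- function(eta, clip = 12) pmin(pmax(eta, -clip), clip)

.inv_logit <- function(eta) stats::plogis(eta)

.logit <- function(p) stats::qlogis(p)

# log(sum(exp(x))) along rows of a matrix, max-shift stabilized
.row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Standardized month basis
#'
#' Powers of the standardized month index used as the polynomial basis for
#' trajectory linear predictors. Months \code{1..n_months} are centered and
#' scaled by their population standard deviation (for 12 months: mean 6.5,
#' sd ~= 3.452), so that polynomial fits up to quintic order stay well
#' conditioned. Wald tests on a group's highest-order coefficient are
#' invariant to this affine rescaling.
#'
#' @param months integer vector of month indices (1-based).
#' @param order polynomial order (0 = intercept only).
#' @param n_months number of months in the panel (defines the scaling).
#' @return numeric matrix with \code{length(months)} rows and
#'   \code{order + 1} columns; column j holds the (j-1)-th power.
#' @export
month_basis <- function(months, order, n_months = 12L) {
  stopifnot(order >= 0L, n_months >= 1L, all(months >= 1L), all(months <= n_months))
  mu <- mean(seq_len(n_months))
  sd_pop <- sqrt(mean((seq_len(n_months) - mu)^2))
  if (sd_pop == 0) sd_pop <- 1  # single-month panel: intercept-only basis
  z <- (months - mu) / sd_pop
  outer(z, 0:order, `^`)
}

.assert_binary_panel <- function(panel) {
  if (!is.matrix(panel)) panel <- as.matrix(panel)
  if (nrow(panel) == 0L) stop("panel is empty", call. = FALSE)
  if (anyNA(panel) || !all(panel %in% c(0, 1))) {
    stop("panel must contain only 0/1 values", call. = FALSE)
  }
  storage.mode(panel) <- "double"
  panel
}

.require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("table '%s' is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
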