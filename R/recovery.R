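#' Match fitted groups to generating groups by trajectory means
#'
#' Mixture components are identified only up to relabeling. This resolves
#' label switching by choosing the permutation of fitted groups that
#' minimizes the total squared distance between fitted monthly adherence
#' probability curves and the scenario's generating curves.
#'
#' @param fit a fitted \code{"adtraj_gbtm"} with the same group count as
#'   the scenario.
#' @param scn the generating [scenario()].
#' @return integer vector \code{perm} such that fitted group
#'   \code{perm[g]} corresponds to generating group g; attributes carry the
#'   matched distance matrix.
#' @export
match_groups <- function(fit, scn) {
  stopifnot(inherits(fit, "adtraj_gbtm"), inherits(scn, "adtraj_scenario"))
  G <- fit$spec$G
  if (G != length(scn$group_probs)) {
    stop("fit and scenario have different group counts", call. = FALSE)
  }
  truth <- scenario_trajectory_probs(scn)              # T x G
  fitted <- .traj_probs(fit$params$beta, fit$n_months) # T x G
  D <- matrix(0, G, G)  # D[g, h] = distance truth g vs fitted h
  for (g in seq_len(G)) for (h in seq_len(G)) {
    D[g, h] <- sum((truth[, g] - fitted[, h])^2)
  }
  perms <- .permutations(G)
  costs <- vapply(seq_len(nrow(perms)), function(r) {
    sum(D[cbind(seq_len(G), perms[r, ])])
  }, numeric(1))
  perm <- perms[which.min(costs), ]
  attr(perm, "distance") <- D
  perm
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
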