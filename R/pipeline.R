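#' Group-stratified descriptive summary
#'
#' Per-group means/SDs for numeric covariates and counts/percentages for
#' categorical ones, with one-way ANOVA p-values (continuous) and
#' chi-squared p-values (categorical) across groups. Constant columns and
#' single-group inputs skip the tests with a flag.
#'
#' @param covariates data.frame of baseline covariates (a
#'   \code{patient_id} column is ignored).
#' @param labels assigned group labels aligned with the covariate rows.
#' @return data.frame with one row per covariate (or factor level):
#'   variable, level, per-group summaries, test, p, flag.
#' @export
summarize_groups <- function(covariates, labels) {
  stopifnot(nrow(covariates) == length(labels))
  groups <- sort(unique(labels))
  single <- length(groups) < 2L
  vars <- setdiff(names(covariates), "patient_id")
  rows <- list()
  for (v in vars) {
    x <- covariates[[v]]
    if (is.character(x)) x <- factor(x)
    if (is.factor(x)) {
      tab <- table(x, factor(labels, levels = groups))
      p <- NA_real_; flag <- ""
      if (single) {
        flag <- "single group; test skipped"
      } else if (nrow(tab) < 2L) {
        flag <- "constant column; test skipped"
      } else {
        p <- suppressWarnings(stats::chisq.test(tab)$p.value)
      }
      for (lv in rownames(tab)) {
        cnt <- tab[lv, ]
        pct <- 100 * cnt / pmax(colSums(tab), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lv,
          summary = paste(sprintf("%d (%.1f%%)", cnt, pct), collapse = " | "),
          test = "chisq", p = p, flag = flag)
      }
    } else {
      x <- as.numeric(x)
      m <- tapply(x, factor(labels, levels = groups), mean, na.rm = TRUE)
      s <- tapply(x, factor(labels, levels = groups), stats::sd, na.rm = TRUE)
      p <- NA_real_; flag <- ""
      if (single) {
        flag <- "single group; test skipped"
      } else if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
        flag <- "constant column; test skipped"
      } else {
        p <- stats::anova(stats::lm(x ~ factor(labels)))[["Pr(>F)"]][1]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "",
        summary = paste(sprintf("%.2f (%.2f)", m, s), collapse = " | "),
        test = "anova", p = p, flag = flag)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "group_sizes") <- as.integer(table(factor(labels, levels = groups)))
  out
}

#' Run the full adherence-trajectory pipeline
#'
#' simulate -> cohort filters -> adherence (PDC from claims) -> model
#' selection -> diagnostics -> membership regression, writing each stage's
#' artifact as plain text (CSV/JSON) plus a manifest with the seed, stage
#' timings and input hashes so a run is reproducible and each intermediate
#' independently inspectable.
#'
#' @param config list with elements:
#'   \code{scenario} (an \code{"adtraj_scenario"} or registry name),
#'   \code{outdir} (output directory), \code{seed},
#'   \code{fit} (list: starts, tol, max_iter),
#'   \code{selection} (list: max_groups, max_order, alpha, min_share),
#'   \code{covariate_vars} (columns for the membership regression; NULL
#'   selects all numeric covariates),
#'   \code{stages} (subset of
#'   c("simulate","cohort","adherence","select","diagnose","regress");
#'   defaults to all; later stages read earlier artifacts from
#'   \code{outdir}),
#'   \code{panel_source} ("simulated" fits the generator's drawn panel,
#'   "claims" fits the panel recomputed from fills, default).
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(list(
    scenario = "nintedanib5", outdir = "adtraj_run", seed = 1L,
    fit = list(starts = 10L, tol = 1e-7, max_iter = 500L),
    selection = list(max_groups = 5L, max_order = 5L, alpha = 0.05,
                     min_share = 0.05),
    covariate_vars = NULL,
    stages = c("simulate", "cohort", "adherence", "select", "diagnose",
               "regress"),
    panel_source = "claims"
  ), config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  t_start <- list()
  timings <- list()
  tic <- function(nm) t_start[[nm]] <<- Sys.time()
  toc <- function(nm) timings[[nm]] <<-
    as.numeric(difftime(Sys.time(), t_start[[nm]], units = "secs"))
  res <- list()
  pth <- function(f) file.path(cfg$outdir, f)

  scn <- if (inherits(cfg$scenario, "adtraj_scenario")) cfg$scenario
         else default_scenario(cfg$scenario, seed = cfg$seed)

  if ("simulate" %in% cfg$stages) {
    tic("simulate")
    res$cohort <- simulate_cohort(scn)
    write_cohort(res$cohort, cfg$outdir)
    write_scenario(scn, pth("scenario.json"))
    toc("simulate")
  }

  read_tables <- function() {
    need <- c("covariates.csv", "fills.csv", "enrollment.csv", "diagnoses.csv")
    miss <- need[!file.exists(pth(need))]
    if (length(miss)) {
      stop(sprintf("missing pipeline input(s) in %s: %s", cfg$outdir,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    list(covariates = utils::read.csv(pth("covariates.csv")),
         fills = utils::read.csv(pth("fills.csv")),
         enrollment = utils::read.csv(pth("enrollment.csv")),
         diagnoses = utils::read.csv(pth("diagnoses.csv")))
  }

  if ("cohort" %in% cfg$stages) {
    tic("cohort")
    tables <- read_tables()
    res$filter <- apply_filters(tables)
    utils::write.csv(res$filter$attrition, pth("attrition.csv"),
                     row.names = FALSE)
    toc("cohort")
  }

  if ("adherence" %in% cfg$stages) {
    tic("adherence")
    if (!file.exists(pth("fills.csv"))) {
      stop(sprintf("missing pipeline input in %s: fills.csv", cfg$outdir),
           call. = FALSE)
    }
    fills <- utils::read.csv(pth("fills.csv"))
    keep <- if (!is.null(res$filter)) res$filter$patient_ids else
      unique(fills$patient_id)
    res$adherence <- compute_adherence(fills[fills$patient_id %in% keep, ],
                                       horizon = 30L * scn$n_months)
    utils::write.csv(res$adherence$long, pth("adherence.csv"),
                     row.names = FALSE)
    toc("adherence")
  }

  get_panel <- function() {
    if (cfg$panel_source == "claims" && !is.null(res$adherence)) {
      return(res$adherence$panel)
    }
    if (!file.exists(pth("panel.csv"))) {
      stop(sprintf("missing pipeline input in %s: panel.csv", cfg$outdir),
           call. = FALSE)
    }
    pdf <- utils::read.csv(pth("panel.csv"))
    as.matrix(pdf[, grep("^m[0-9]+$", names(pdf)), drop = FALSE])
  }

  if ("select" %in% cfg$stages) {
    tic("select")
    panel <- get_panel()
    res$selection <- select_model(
      panel,
      max_groups = cfg$selection$max_groups,
      max_order = cfg$selection$max_order,
      alpha = cfg$selection$alpha, min_share = cfg$selection$min_share,
      starts = cfg$fit$starts, seed = cfg$seed, tol = cfg$fit$tol,
      max_iter = cfg$fit$max_iter)
    utils::write.csv(res$selection$grid, pth("grid.csv"), row.names = FALSE)
    fit <- res$selection$final_fit
    jsonlite::write_json(list(
      seed = cfg$seed,
      G = fit$spec$G, orders = fit$spec$orders,
      pi = fit$params$pi, beta = fit$params$beta,
      loglik = fit$loglik, bic = fit$bic, k = fit$k,
      converged = fit$convergence$converged,
      reduction_steps = nrow(res$selection$reduction_trace),
      min_share_ok = res$selection$min_share_ok
    ), pth("selection.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(
      data.frame(patient = seq_len(nrow(fit$posteriors)),
                 label = fit$labels, fit$posteriors |>
                   `colnames<-`(paste0("p", seq_len(fit$spec$G)))),
      pth("posteriors.csv"), row.names = FALSE)
    toc("select")
  }

  if ("diagnose" %in% cfg$stages) {
    tic("diagnose")
    if (is.null(res$selection)) stop("diagnose stage requires select stage",
                                     call. = FALSE)
    panel <- get_panel()
    res$diagnostics <- model_diagnostics(res$selection$final_fit, panel)
    d <- res$diagnostics
    jsonlite::write_json(list(
      seed = cfg$seed,
      app = as.numeric(d$app), occ = as.numeric(d$occ), pi = d$pi,
      assigned_share = d$assigned_share,
      relative_entropy = d$relative_entropy,
      pass = as.list(d$pass)
    ), pth("diagnostics.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(d$trajectories, pth("trajectories.csv"),
                     row.names = FALSE)
    utils::write.csv(d$spaghetti, pth("spaghetti.csv"), row.names = FALSE)
    toc("diagnose")
  }

  if ("regress" %in% cfg$stages) {
    tic("regress")
    if (is.null(res$selection)) stop("regress stage requires select stage",
                                     call. = FALSE)
    if (!file.exists(pth("covariates.csv"))) {
      stop(sprintf("missing pipeline input in %s: covariates.csv", cfg$outdir),
           call. = FALSE)
    }
    covs <- utils::read.csv(pth("covariates.csv"))
    fit <- res$selection$final_fit
    ids <- as.integer(rownames(fit$posteriors))
    if (!length(ids) || anyNA(ids)) ids <- seq_len(nrow(fit$posteriors))
    covs <- covs[match(ids, covs$patient_id), , drop = FALSE]
    vars <- cfg$covariate_vars
    if (is.null(vars)) {
      vars <- setdiff(names(covs)[vapply(covs, is.numeric, TRUE)],
                      c("patient_id", "death_day"))
    }
    X <- membership_design(covs, vars)
    res$fmlogit <- fit_fmlogit(fit$posteriors, X, ref_group = 1L)
    res$aor <- aor_table(res$fmlogit)
    utils::write.csv(res$aor, pth("aor_table.csv"), row.names = FALSE)
    sm <- summarize_groups(covs, fit$labels)
    utils::write.csv(sm, pth("group_summary.csv"), row.names = FALSE)
    toc("regress")
  }

  inputs <- list.files(cfg$outdir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("adtraj")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    stages = cfg$stages,
    timings_sec = timings,
    file_md5 = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(res)
}
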