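#' Default discriminant-model roster
#'
#' The comparisons analysed throughout the flow-chamber study: six binary
#' models between conditions, ternary Healthy/T1D/T2D models with 6, 5, 4
#' and 3 fixed variables, the TNF-activated ternary model, and the 6-group
#' model. Each entry carries the published fixed variable list (translated
#' to the package's column names) used in \code{"reproduce"} mode; in
#' \code{"discover"} mode the list is ignored and stepwise selection runs
#' afresh.
#'
#' @return Named list of model specs (\code{groups}: condition labels;
#'   \code{variables}: fixed list or NULL).
#' @export
default_model_roster <- function() {
  H <- "Healthy"; HT <- "Healthy+TNF"; T1 <- "T1D"; T1T <- "T1D+TNF"
  T2 <- "T2D"; T2T <- "T2D+TNF"
  list(
    healthy_vs_healthy_tnf = list(groups = c(H, HT),
      variables = "prod_v_500_1000_x_1000_1500"),
    healthy_vs_t1d = list(groups = c(H, T1),
      variables = c("prod_va_med", "prod_a_minf_m5000_x_0_5000", "N_v_500_1000")),
    healthy_tnf_vs_t1d = list(groups = c(HT, T1),
      variables = c("v_med", "prod_v_500_1000_x_1000_1500")),
    healthy_vs_t2d = list(groups = c(H, T2),
      variables = c("R_ratio", "prod_v_0_500_x_1000_1500",
                    "prod_a_m5000_0_x_5000_inf")),
    healthy_tnf_vs_t2d = list(groups = c(HT, T2),
      variables = c("a_m5000_0", "prod_v_500_1000_x_1000_1500")),
    t1d_vs_t2d = list(groups = c(T1, T2),
      variables = c("prod_v_0_500_x_500_1000", "R_ratio", "v_ave")),
    ternary_6var = list(groups = c(H, T1, T2),
      variables = c("N_v_500_1000", "N_v_1000_1500",
                    "prod_v_0_500_x_500_1000", "R_ratio", "v_ave",
                    "a_minf_m5000")),
    ternary_5var = list(groups = c(H, T1, T2),
      variables = c("N_v_500_1000", "N_v_1000_1500",
                    "prod_v_0_500_x_500_1000", "R_ratio", "v_ave")),
    ternary_4var = list(groups = c(H, T1, T2),
      variables = c("N_v_500_1000", "N_v_1000_1500",
                    "prod_v_0_500_x_500_1000", "R_ratio")),
    ternary_3var = list(groups = c(H, T1, T2),
      variables = c("N_v_500_1000", "N_v_1000_1500", "R_ratio")),
    ternary_tnf = list(groups = c(HT, T1T, T2T),
      variables = c("v_500_1000", "v_1500_inf", "N_a_5000_inf")),
    six_group = list(groups = c(H, HT, T1, T1T, T2, T2T),
      variables = c("N_v_500_1000", "R_ratio", "v_ave"))
  )
}

#' Pipeline configuration
#'
#' @param mode Input mode: \code{"simulate"} (run the cohort simulator),
#'   \code{"cohort-csv"} (read a prepared cohort table) or
#'   \code{"tracker-files"} (read a directory of trajectory exports, one
#'   file per recording, named \code{<id>_<group>_<basal|tnf>.tsv}).
#' @param path Input path for the file-based modes.
#' @param sim A \code{\link{simulation_config}} for \code{"simulate"} mode.
#' @param roster Model roster (see \code{\link{default_model_roster}}).
#' @param lda_mode \code{"reproduce"} (fixed variable lists) or
#'   \code{"discover"} (fresh stepwise selection per model).
#' @param f_in,f_out Stepwise thresholds.
#' @param priors \code{"equal"} or \code{"proportional"} group priors.
#' @param bins A \code{\link{bin_scheme}}.
#' @param calibration A \code{\link{calibration_spec}}.
#' @param seed Integer seed.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(mode = c("simulate", "cohort-csv", "tracker-files"),
                            path = NULL, sim = simulation_config(),
                            roster = default_model_roster(),
                            lda_mode = c("reproduce", "discover"),
                            f_in = 3.84, f_out = 2.71,
                            priors = c("equal", "proportional"),
                            bins = bin_scheme(),
                            calibration = calibration_spec(), seed = 1L) {
  mode <- match.arg(mode)
  lda_mode <- match.arg(lda_mode)
  priors <- match.arg(priors)
  if (mode != "simulate" && is.null(path))
    stop("config error: path required for mode ", mode, call. = FALSE)
  if (!length(roster)) stop("config error: empty model roster", call. = FALSE)
  structure(list(mode = mode, path = path, sim = sim, roster = roster,
                 lda_mode = lda_mode, f_in = f_in, f_out = f_out,
                 priors = priors, bins = bins, calibration = calibration,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

condition_label <- function(cohort) {
  paste0(cohort$group, ifelse(cohort$tnf, "+TNF", ""))
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)  # scratch only; the hash is what persists
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (simulation or ingest), descriptor
#' extraction (already embedded in the cohort for file modes), univariate
#' group statistics, PCA, and every discriminant model of the roster
#' (Wilks' lambda, standardized coefficients, VIF, original and
#' leave-one-out accuracy). Identical configuration and seed give an
#' identical report.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return A list of class \code{run_report}: \code{cohort},
#'   \code{models} (per roster entry), \code{anova}, \code{pca} and
#'   \code{provenance}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- switch(config$mode,
    "simulate" = simulate_cohort(config$sim)$cohort,
    "cohort-csv" = utils::read.csv(config$path, check.names = FALSE),
    "tracker-files" = .ingest_tracker_dir(config$path, config$calibration))
  if (!all(c("group", "tnf") %in% names(cohort)))
    stop("data error: cohort lacks group/tnf columns", call. = FALSE)
  cohort$tnf <- as.logical(cohort$tnf)
  lab6 <- condition_label(cohort)
  feats <- intersect(feature_names(), names(cohort))
  classical <- intersect(c("rolling_velocity", "rolling_flux", "adhesion"),
                         names(cohort))

  an <- anova_tukey(cohort, c(classical, feats))
  pca <- suppressWarnings(pca_varimax(cohort[, feats, drop = FALSE]))

  models <- list()
  for (nm in names(config$roster)) {
    spec <- config$roster[[nm]]
    rows <- lab6 %in% spec$groups
    if (sum(rows) < 4 || length(unique(lab6[rows])) < 2) {
      warning("model ", nm, " skipped: groups not present", call. = FALSE)
      next
    }
    Xm <- cohort[rows, feats, drop = FALSE]
    ym <- factor(lab6[rows], levels = spec$groups)
    vars <- spec$variables
    sel <- NULL
    if (config$lda_mode == "discover" || is.null(vars)) {
      sel <- stepwise_select(Xm, ym, f_in = config$f_in, f_out = config$f_out)
      vars <- sel$selected
    }
    vars <- intersect(vars, names(Xm))
    if (!length(vars)) {
      models[[nm]] <- list(variables = character(0), skipped = "no variables")
      next
    }
    priors <- if (config$priors == "proportional")
      table(ym) / length(ym) else NULL
    models[[nm]] <- tryCatch({
      fit <- fit_classifier(Xm, ym, vars, priors)
      orig <- .cv_result(ym, predict(fit, Xm), levels(ym))
      cv <- loo_cv(Xm, ym, vars, priors)
      list(variables = vars, selection = sel, fit = fit,
           wilks_lambda = fit$wilks_lambda, vif = fit$vif,
           original = orig, loo = cv)
    }, error = function(e) {
      warning("model ", nm, " failed: ", conditionMessage(e), call. = FALSE)
      list(variables = vars, skipped = conditionMessage(e))
    })
  }

  structure(list(cohort = cohort, models = models, anova = an, pca = pca,
                 provenance = list(config_hash = .config_hash(config),
                                   seed = config$seed,
                                   mode = config$mode,
                                   lda_mode = config$lda_mode,
                                   package_version = as.character(
                                     utils::packageVersion("leukoflow")),
                                   timestamp = NA)),
            class = "run_report")
}

.ingest_tracker_dir <- function(path, calibration) {
  files <- list.files(path, full.names = TRUE)
  if (!length(files)) stop("data error: no files in ", path, call. = FALSE)
  rows <- lapply(files, function(f) {
    parts <- strsplit(sub("\\.[^.]*$", "", basename(f)), "_")[[1]]
    if (length(parts) < 3)
      stop("data error: expected <id>_<group>_<basal|tnf> file names", call. = FALSE)
    rec <- parse_tracker_export(f, calibration, individual_id = parts[1],
                                group = parts[2],
                                tnf = identical(parts[3], "tnf"))
    feats <- novel_features(rec)
    cls <- classical_parameters(rec)
    data.frame(individual_id = parts[1], group = parts[2],
               tnf = identical(parts[3], "tnf"),
               rolling_velocity = cls$rolling_velocity,
               rolling_flux = cls$rolling_flux, adhesion = cls$adhesion,
               as.list(unclass(feats)[feature_names()]), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d cohort rows, %d model(s)\n",
              nrow(x$cohort), length(x$models)))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    if (!is.null(m$skipped)) { cat(sprintf("  %s: skipped\n", nm)); next }
    cat(sprintf("  %s: lambda=%.3f, LOO=%.0f%%, vars=%s\n", nm,
                m$wilks_lambda, m$loo$overall_accuracy,
                paste(m$variables, collapse = ",")))
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits a deterministic set of text artifacts: a human-readable summary,
#' one CSV per model (variables, standardized coefficients, VIF,
#' accuracies), tidy ANOVA/Tukey tables, and a provenance file.
#'
#' @param report A \code{run_report}.
#' @param outdir Output directory (created if needed; must be writable).
#' @return Character vector of written file paths, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("I/O error: cannot create ", outdir, call. = FALSE)
  if (file.access(outdir, 2) != 0)
    stop("I/O error: unwritable directory ", outdir, call. = FALSE)
  written <- character(0)
  wf <- function(name) { p <- file.path(outdir, name); written <<- c(written, p); p }

  # summary
  con <- file(wf("summary.txt"), "w")
  sink(con); print(report); sink(); close(con)

  # per-model tables
  for (nm in names(report$models)) {
    m <- report$models[[nm]]
    if (!is.null(m$skipped)) next
    std <- m$fit$standardized_coefficients
    df <- data.frame(variable = m$variables,
                     std, VIF = m$vif,
                     wilks_lambda = m$wilks_lambda,
                     loo_overall = m$loo$overall_accuracy,
                     row.names = NULL, check.names = FALSE)
    utils::write.csv(df, wf(paste0("model_", nm, ".csv")), row.names = FALSE)
  }
  if (!is.null(report$anova$anova))
    utils::write.csv(report$anova$anova, wf("anova.csv"), row.names = FALSE)
  if (!is.null(report$anova$tukey))
    utils::write.csv(report$anova$tukey, wf("tukey.csv"), row.names = FALSE)

  prov <- report$provenance
  writeLines(c(paste0("config_hash: ", prov$config_hash),
               paste0("seed: ", prov$seed),
               paste0("mode: ", prov$mode),
               paste0("lda_mode: ", prov$lda_mode),
               paste0("package_version: ", prov$package_version)),
             wf("provenance.txt"))
  invisible(written)
}
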