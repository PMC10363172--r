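#' Read a concentration table
#'
#' The interchange dialect is a UTF-8 CSV with header columns `subject_id`,
#' `group_label`, `formulation`, `dose_mg_per_kg`, `analyte`, `time_h`,
#' `conc_ng_per_ml`, `blq` (0/1); the concentration cell is empty exactly on
#' censored rows (`blq = 1`; a stored censoring bound is also accepted).
#' Unknown columns are preserved but ignored. Rows are sorted by subject,
#' analyte, time.
#'
#' @param path Path to a CSV file.
#' @return A validated, sorted data.frame.
#' @export
read_concentration_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("subject_id", "group_label", "formulation", "dose_mg_per_kg",
                "analyte", "time_h", "conc_ng_per_ml", "blq")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop("concentration table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!nrow(d)) {
    warning("concentration table ", path, " has a header but no rows")
    return(d)
  }
  d$time_h <- as.numeric(d$time_h)
  d$conc_ng_per_ml <- as.numeric(d$conc_ng_per_ml)
  d$dose_mg_per_kg <- as.numeric(d$dose_mg_per_kg)
  d$blq <- as.integer(d$blq)
  if (any(is.na(d$time_h)) || any(d$time_h < 0)) stop("negative or missing time_h")
  if (any(!is.na(d$conc_ng_per_ml) & d$conc_ng_per_ml < 0)) {
    stop("negative concentration")
  }
  if (!all(d$blq %in% c(0L, 1L))) stop("blq must be 0 or 1")
  bad_blq <- is.na(d$conc_ng_per_ml) & d$blq == 0L
  if (any(bad_blq)) {
    stop("missing concentration on quantifiable (blq=0) rows: ",
         paste(which(bad_blq), collapse = ", "))
  }
  key <- paste(d$subject_id, d$analyte, d$time_h, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    ex <- d[dup, c("subject_id", "analyte", "time_h")][1L, ]
    stop(sprintf("duplicate (subject, analyte, time) rows, e.g. %s/%s at %g h (rows %s)",
                 ex$subject_id, ex$analyte, ex$time_h,
                 paste(which(key %in% key[dup]), collapse = ", ")))
  }
  d <- d[order(d$subject_id, d$analyte, d$time_h), ]
  rownames(d) <- NULL
  message(sprintf("read %d rows, %d subjects, %d analytes from %s",
                  nrow(d), length(unique(d$subject_id)),
                  length(unique(d$analyte)), path))
  d
}

#' Write a concentration table
#'
#' Inverse of [read_concentration_table()]: censored rows are written with an
#' empty concentration cell. Round-trip is the identity on canonical tables.
#'
#' @param table A concentration table data.frame.
#' @param path Output CSV path.
#' @export
write_concentration_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a run configuration
#'
#' A JSON document with members `seed`, `design` (groups, schedule_h,
#' lloq_ng_per_ml, threshold_ng_per_ml), `population` (typical, bsv_cv,
#' residual_cv, metabolite) and optional `nca` (lambda_z_min_points,
#' adj_r2_tol, clast_mode, extrapolation_warn_pct, threshold) and
#' `comparisons` (parameters, pairs, family_size, alpha) members. Ships with
#' a reference configuration at
#' `system.file("extdata", "study_config.json", package = "depotnca")`.
#'
#' @param path Path to the JSON config.
#' @return A list of class `run_config` with validated `design`
#'   ([study_design()]), `population` ([population_params()]), `nca`
#'   ([nca_options()]), `comparisons` and `seed` members.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (need in c("seed", "design", "population")) {
    if (is.null(raw[[need]])) stop("config is missing '", need, "'")
  }
  des <- raw$design
  design <- study_design(
    groups = as.data.frame(des$groups),
    schedule_h = des$schedule_h,
    lloq_ng_per_ml = des$lloq_ng_per_ml %||% 0.1,
    threshold_ng_per_ml = des$threshold_ng_per_ml %||% 0.1
  )
  popr <- raw$population
  typ <- popr$typical
  met <- if (!is.null(popr$metabolite)) {
    metabolite_params(popr$metabolite$fm, popr$metabolite$volume_m_over_F,
                      popr$metabolite$ke_m)
  }
  pop <- population_params(
    typical = pk_parameters(typ$clearance_over_F, typ$volume_over_F,
                            typ$ka_fast, typ$ka_slow, typ$frac_fast %||% 1),
    bsv_cv = unlist(popr$bsv_cv %||% list()),
    residual_cv = popr$residual_cv %||% 0,
    metabolite = met
  )
  ncar <- raw$nca %||% list()
  nca <- nca_options(
    lambda_z_min_points = ncar$lambda_z_min_points %||% 3L,
    adj_r2_tol = ncar$adj_r2_tol %||% 1e-4,
    clast_mode = ncar$clast_mode %||% "observed",
    extrapolation_warn_pct = ncar$extrapolation_warn_pct %||% 20,
    threshold = ncar$threshold %||% design$threshold_ng_per_ml
  )
  cmpr <- raw$comparisons %||% list()
  comparisons <- list(
    parameters = cmpr$parameters %||% table1_parameters(),
    pairs = if (!is.null(cmpr$pairs)) {
      if (is.matrix(cmpr$pairs)) {
        lapply(seq_len(nrow(cmpr$pairs)), function(i) cmpr$pairs[i, ])
      } else {
        cmpr$pairs
      }
    },
    family_size = cmpr$family_size %||% 1,
    alpha = cmpr$alpha %||% 0.05
  )
  structure(list(seed = as.integer(raw$seed), design = design,
                 population = pop, nca = nca, comparisons = comparisons),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Serialise the resolved configuration (fully expanded defaults) next to the
# outputs so every run is reproducible from its own artifacts.
resolved_config_json <- function(config) {
  pop <- config$population
  met <- pop$metabolite
  out <- list(
    seed = config$seed,
    design = list(groups = config$design$groups,
                  schedule_h = config$design$schedule_h,
                  lloq_ng_per_ml = config$design$lloq_ng_per_ml,
                  threshold_ng_per_ml = config$design$threshold_ng_per_ml),
    population = list(
      typical = unclass(pop$typical),
      bsv_cv = as.list(pop$bsv_cv),
      residual_cv = pop$residual_cv,
      metabolite = if (!is.null(met)) unclass(met)),
    nca = unclass(config$nca),
    comparisons = config$comparisons
  )
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   null = "null")
}

#' Write the full result set of a pipeline run
#'
#' Emits per-subject NCA results (CSV and JSON), the group parameter summary
#' (CSV plus a human-readable text table), per-group mean curves, the
#' threshold report, between-group comparisons, the resolved configuration
#' and a log. Given identical inputs and configuration, every file except the
#' log (which carries a timestamp) is byte-identical across runs.
#'
#' @param outdir Output directory, created if needed.
#' @param results data.frame from [run_nca_table()].
#' @param summaries data.frame from [summarize_parameters()], or `NULL`.
#' @param comparisons data.frame from [compare_groups()], or `NULL`.
#' @param mean_curves data.frame of stacked [mean_sd_curve()] rows, or `NULL`.
#' @param thresholds data.frame from [threshold_report()], or `NULL`.
#' @param config A `run_config`, or `NULL`.
#' @param log_lines Character vector appended to the run log.
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(outdir, results, summaries = NULL,
                          comparisons = NULL, mean_curves = NULL,
                          thresholds = NULL, config = NULL,
                          log_lines = character()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(d, name) {
    p <- file.path(outdir, name)
    utils::write.csv(d, p, row.names = FALSE, na = "", fileEncoding = "UTF-8")
    files <<- c(files, p)
  }
  wr(results, "nca_results.csv")
  p <- file.path(outdir, "nca_results.json")
  jsonlite::write_json(results, p, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, p)
  if (!is.null(summaries)) {
    wr(summaries, "summary_parameters.csv")
    txt <- format_group_summary(summaries)
    p <- file.path(outdir, "summary_parameters.txt")
    writeLines(c("Group parameter summary (mean ± SD)", "",
                 utils::capture.output(print(txt, quote = FALSE))),
               p, useBytes = FALSE)
    files <- c(files, p)
  }
  if (!is.null(mean_curves)) wr(mean_curves, "mean_curves.csv")
  if (!is.null(thresholds)) wr(thresholds, "threshold_report.csv")
  if (!is.null(comparisons)) wr(comparisons, "comparisons.csv")
  if (!is.null(config)) {
    p <- file.path(outdir, "resolved_config.json")
    writeLines(resolved_config_json(config), p)
    files <- c(files, p)
  }
  p <- file.path(outdir, "run.log")
  writeLines(c(sprintf("depotnca %s | %s",
                       as.character(utils::packageVersion("depotnca")),
                       format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               log_lines), p)
  invisible(c(files, p))
}
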