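#' Write a recruitment curve to CSV
#'
#' Columns `time_s, value, kind, r0_um, D_um2_s` (comma separated, '.'
#' decimal separator, UTF-8, header mandatory); numeric values written with
#' 12 significant digits so curves round-trip losslessly at that precision.
#' Extra columns read by [read_curve()] are preserved on rewrite.
#'
#' @param curve a `recruitment_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "recruitment_curve"))
  r0 <- attr(curve, "r0")
  r0_num <- if (is.numeric(r0) && length(r0) == 1L) r0
            else if (inherits(r0, "start_distribution")) r0$mean
            else NA_real_
  d <- data.frame(
    time_s = sprintf("%.12g", curve$time_s),
    value = sprintf("%.12g", curve$fraction),
    kind = attr(curve, "kind"),
    r0_um = sprintf("%.12g", r0_num),
    D_um2_s = sprintf("%.12g", if (is.null(attr(curve, "D"))) NA_real_
                      else attr(curve, "D")),
    stringsAsFactors = FALSE)
  extra <- attr(curve, "extra_columns")
  if (!is.null(extra)) d <- cbind(d, extra)
  write.csv(d, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a recruitment curve from CSV
#'
#' Expects the [write_curve()] dialect.  The time column must be strictly
#' increasing (a format error names the offending row otherwise); fractions
#' above 1.05 trigger a validation warning but are retained.
#'
#' @param path input file path.
#' @return A `recruitment_curve`; unknown extra columns are kept in the
#'   `extra_columns` attribute.
#' @export
read_curve <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("format error: empty or missing curve file: ", path, call. = FALSE)
  d <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                error = function(e)
                  stop("format error reading ", path, ": ",
                       conditionMessage(e), call. = FALSE))
  need <- c("time_s", "value", "kind", "r0_um", "D_um2_s")
  if (nrow(d) == 0 || !all(need %in% names(d)))
    stop("format error: curve file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- which(diff(d$time_s) <= 0)
  if (length(bad))
    stop("format error: time column not strictly increasing at row ",
         bad[1] + 1L, call. = FALSE)
  if (any(d$value > 1.05))
    warning("curve values exceed 1.05 (retained)", call. = FALSE)
  kind <- d$kind[1]
  if (!kind %in% c("analytic", "simulated", "synthetic", "observed"))
    kind <- "observed"
  cv <- recruitment_curve(d$time_s, pmin(d$value, 1.05),
                          kind = kind,
                          r0 = if (is.finite(d$r0_um[1])) d$r0_um[1] else NULL,
                          D = if (is.finite(d$D_um2_s[1])) d$D_um2_s[1]
                              else NULL)
  # out-of-range values are warned about above but retained verbatim
  cv$fraction <- d$value
  extra <- d[setdiff(names(d), need)]
  if (ncol(extra)) attr(cv, "extra_columns") <- extra
  cv
}

#' Write a first-passage-time ensemble to CSV
#'
#' Columns `replica_id, r0_um, fpt_s, censored` (booleans as true/false).
#'
#' @param ensemble an `fpt_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fpt <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "fpt_ensemble"))
  d <- data.frame(replica_id = seq_len(ensemble$n),
                  r0_um = sprintf("%.12g", rep_len(ensemble$r0, ensemble$n)),
                  fpt_s = sprintf("%.12g", ensemble$times),
                  censored = ifelse(ensemble$censored, "true", "false"))
  write.csv(d, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a first-passage-time ensemble from CSV
#'
#' @param path input file path (dialect of [write_fpt()]).
#' @param horizon censoring horizon, seconds; defaults to the maximum
#'   censored time in the file (or the maximum time if none are censored).
#' @return An `fpt_ensemble`.
#' @export
read_fpt <- function(path, horizon = NULL) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("format error: empty or missing FPT file: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("replica_id", "r0_um", "fpt_s", "censored")
  if (!all(need %in% names(d)))
    stop("format error: FPT file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  cens <- tolower(as.character(d$censored)) %in% c("true", "t", "1")
  if (is.null(horizon))
    horizon <- if (any(cens)) max(d$fpt_s[cens]) else max(d$fpt_s)
  fpt_ensemble(d$fpt_s, cens, horizon, r0 = d$r0_um)
}

#' Read a pipeline configuration
#'
#' YAML with blocks `geometry` (`R_um`, `ra_um`), `protein` (`name`,
#' `D_um2_s`, `r0_mean_um`, `r0_lower_um`, `r0_upper_um`), `lattice`
#' (`preset` or `unit_nm`/`box_um`, `effective_step`), `run` (`replicas`,
#' `horizon_s`, `seed`), `analysis` (`grid`), `inference` (`search`,
#' `step_um`), `synth` (`true_mean_um`, `noise_sd`, `seed`).  Every
#' stochastic stage must carry an explicit seed; absent seeds are an error
#' at the point of use, never an implicit default.
#'
#' @param path YAML file path.
#' @return The configuration list, classed `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' Serialise a configuration back to YAML text
#'
#' `read_config()` of a written config returns the same object
#' (round-trip contract).
#'
#' @param config a `run_config` (or plain list).
#' @param path optional output path; when `NULL` the YAML text is returned.
#' @return The YAML text (invisibly when written to `path`).
#' @export
write_config <- function(config, path = NULL) {
  txt <- yaml::as.yaml(unclass(config))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

config_geometry <- function(config) {
  g <- config$geometry
  if (is.null(g)) cell_geometry()
  else cell_geometry(g$R_um %||% 25, g$ra_um %||% 5)
}

config_protein <- function(config, geometry) {
  p <- config$protein
  if (is.null(p)) stop("config lacks a protein block", call. = FALSE)
  if (!is.null(p$name) && is.null(p$D_um2_s))
    return(protein_defaults(p$name, geometry))
  protein_spec(p$name %||% "protein", p$D_um2_s,
               p$r0_mean_um, p$r0_lower_um %||% (p$r0_mean_um - 3),
               p$r0_upper_um %||% (p$r0_mean_um + 3), geometry)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the modelling pipeline
#'
#' Executes the requested stages in order and writes every artifact plus a
#' manifest (inputs, seeds, package version, MD5 hashes of all outputs) to
#' `out_dir`.  Identical configuration and seeds give identical output
#' hashes.  Stage dependencies are checked before any computation: `fit`
#' needs an observed curve (from the `synth` stage, the `curves` stage or
#' `config$inference$observed`); `curves` needs an ensemble (from
#' `simulate`).
#'
#' Stages: `theory` (analytic curve), `simulate` (kMC ensemble), `curves`
#' (accumulated simulated curve), `synth` (synthetic curve + truth),
#' `fit` (starting-radius fit).
#'
#' @param config a `run_config` (see [read_config()]).
#' @param stages character subset of
#'   `c("theory", "simulate", "curves", "synth", "fit")`.
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, stages, out_dir) {
  stages <- match.arg(stages, c("theory", "simulate", "curves", "synth",
                                "fit"), several.ok = TRUE)
  # dependency checks before any computation
  if ("curves" %in% stages && !"simulate" %in% stages)
    stop("dependency error: 'curves' requires the 'simulate' stage",
         call. = FALSE)
  if ("fit" %in% stages && !any(c("synth", "curves") %in% stages) &&
      is.null(config$inference$observed))
    stop("dependency error: 'fit' requires a curve ('synth' or 'curves' ",
         "stage, or config$inference$observed)", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geometry <- config_geometry(config)
  protein <- config_protein(config, geometry)
  outputs <- character(0)
  seeds <- list()
  observed <- NULL

  if ("theory" %in% stages) {
    grid <- config$analysis$grid %||% seq(0, 600, by = 5)
    fam <- config$analysis$family %||% "exact"
    dist <- start_distribution(protein$r0_mean, 1, protein$r0_lower,
                               protein$r0_upper, geometry = geometry)
    cv <- averaged_curve(grid, dist, protein$D, geometry, family = fam)
    f <- file.path(out_dir, "theory_curve.csv")
    write_curve(cv, f)
    outputs <- c(outputs, f)
  }
  ensemble <- NULL
  if ("simulate" %in% stages) {
    run <- config$run
    if (is.null(run$seed))
      stop("config error: run$seed is required for the simulate stage",
           call. = FALSE)
    lat <- lattice_preset(config$lattice$preset %||% "coarse", geometry,
                          protein$D)
    ensemble <- run_ensemble(protein, lat, run$replicas %||% 300L,
                             run$horizon_s %||% 1800,
                             base_seed = run$seed,
                             start_mode = run$start_mode %||% "fixed")
    seeds$simulate <- run$seed
    f <- file.path(out_dir, "fpt.csv")
    write_fpt(ensemble, f)
    outputs <- c(outputs, f)
  }
  if ("curves" %in% stages) {
    grid <- config$analysis$grid %||% seq(0, ensemble$horizon,
                                          length.out = 201L)
    cv <- accumulate(ensemble, grid)
    f <- file.path(out_dir, "simulated_curve.csv")
    write_curve(cv, f)
    outputs <- c(outputs, f)
    observed <- cv
  }
  if ("synth" %in% stages) {
    sy <- config$synth
    if (is.null(sy$seed))
      stop("config error: synth$seed is required for the synth stage",
           call. = FALSE)
    spec <- synthetic_spec(protein,
                           true_mean = sy$true_mean_um %||% protein$r0_mean,
                           noise_sd = sy$noise_sd %||% 0.02,
                           seed = sy$seed, geometry = geometry)
    gen <- generate_curve(spec)
    seeds$synth <- sy$seed
    f1 <- file.path(out_dir, "synth_curve.csv")
    f2 <- file.path(out_dir, "synth_truth.json")
    write_curve(gen$curve, f1)
    jsonlite::write_json(gen$truth, f2, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, f1, f2)
    observed <- gen$curve
  }
  if ("fit" %in% stages) {
    if (is.null(observed))
      observed <- read_curve(config$inference$observed)
    inf <- config$inference
    fit <- fit_start_mean(observed, protein,
                          search = unlist(inf$search) %||% NULL,
                          step = inf$step_um %||% 0.25,
                          geometry = geometry)
    f <- file.path(out_dir, "fit.json")
    jsonlite::write_json(list(estimate_um = fit$estimate,
                              objective = fit$objective,
                              grid = fit$grid,
                              diagnostics = fit$diagnostics),
                         f, auto_unbox = TRUE, digits = NA, dataframe = "columns")
    outputs <- c(outputs, f)
  }
  manifest <- list(
    package = "fptrecruit",
    version = as.character(packageVersion("fptrecruit")),
    stages = stages,
    seeds = seeds,
    config = unclass(config),
    outputs = lapply(setNames(outputs, basename(outputs)), function(f)
      list(md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
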