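#' Pipeline run configuration
#'
#' One object holding every tunable of the staged analysis. Exactly one data
#' source must be given: `synthetic` (a [synthetic_spec]) or `dataset`
#' (`"fixture"` or a toxicity CSV path, optionally with `structures`).
#'
#' @param synthetic a [synthetic_spec], or `NULL`
#' @param dataset `"fixture"`, a CSV path, or `NULL`
#' @param structures optional list `list(path=, format=)` for real molecules
#' @param composite list: `mode`, `weight_algae`, `weight_geno`
#' @param prep a [prep_config]
#' @param fields a [field_config]
#' @param pls list: `max_components`, `criterion`, `scramble`,
#'   `scramble_levels`, `n_replicates`, `favored_pct`, `disfavored_pct`
#' @param seed global seed fanned out to the stages
#' @param out_dir output bundle directory
#' @return object of class `run_config`
#' @export
run_config <- function(synthetic = NULL, dataset = NULL, structures = NULL,
                       composite = list(mode = "mean_abs_algae_shared",
                                        weight_algae = 0.8, weight_geno = 0.2),
                       prep = prep_config(), fields = field_config(),
                       pls = list(max_components = 10L, criterion = "q2max",
                                  scramble = FALSE,
                                  scramble_levels = seq(0.1, 1, 0.1),
                                  n_replicates = 20L,
                                  favored_pct = 0.8, disfavored_pct = 0.2),
                       seed = 1L, out_dir = tempfile("duotox_run_")) {
  if (is.null(synthetic) == is.null(dataset)) {
    stop_duotox("give exactly one of synthetic= or dataset=",
                class = "duotox_config_error")
  }
  defaults <- list(max_components = 10L, criterion = "q2max", scramble = FALSE,
                   scramble_levels = seq(0.1, 1, 0.1), n_replicates = 20L,
                   favored_pct = 0.8, disfavored_pct = 0.2)
  for (nm in names(defaults)) pls[[nm]] <- pls[[nm]] %||% defaults[[nm]]
  structure(
    list(synthetic = synthetic, dataset = dataset, structures = structures,
         composite = composite, prep = prep, fields = fields, pls = pls,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full pipeline
#'
#' Stages: data acquisition (synthetic world or toxicity table + structures)
#' -> composite -> preparation/alignment (real molecules only) -> field
#' descriptors -> PLS with LOO, external validation and contributions ->
#' contour extraction -> optional progressive scrambling. The output bundle
#' (model report JSON, scrambling JSON, contour OpenDX files, composite CSV,
#' structured log) is staged in a temporary directory and renamed into place
#' on success, so a crashed run never leaves a half-written bundle at
#' `out_dir`.
#'
#' @param config a [run_config]
#' @return list of class `pipeline_result`: `report` ([fit_qsar()] output),
#'   `contours`, `scrambling` (or `NULL`), `dataset`, `descriptors`,
#'   `out_dir`, `log`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- split_seed(config$seed, 4L)
  log <- character(0)
  say <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(...))
    log <<- c(log, line)
    message(line)
  }

  # --- stage 1: data ---------------------------------------------------------
  molecules <- NULL; planted <- NULL
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    spec$seed <- as.integer(seeds[1L] %% 2147483000L)
    molecules <- generate_molecule_set(spec)
    pa <- plant_activities(molecules, spec, config$fields)
    records <- pa$records
    records$split <- "train"
    planted <- pa$planted
    say("data", "synthetic world: %d molecules, seed %d", length(molecules), spec$seed)
  } else {
    ds <- if (identical(config$dataset, "fixture")) load_table1_fixture() else
      read_toxicity_table(config$dataset)
    cc <- calibrate_standard(ds, mode = config$composite$mode,
                             weight_algae = config$composite$weight_algae,
                             weight_geno = config$composite$weight_geno)
    ds <- composite_table(ds, cc)
    records <- ds$records
    if (is.null(records$split)) records$split <- "train"
    say("data", "%d records, composite standards M1=%.4f M2=%.4f",
        nrow(records), cc$standard_algae, cc$standard_geno)
    if (!is.null(config$structures)) {
      raw <- read_structures(config$structures$path, config$structures$format)
      prepared <- prepare_3d(raw, config$prep, seed = seeds[2L])
      tid <- config$prep$template_id
      if (!tid %in% names(prepared)) {
        stop_duotox("template molecule '", tid, "' not among structures",
                    class = "duotox_config_error")
      }
      template <- prepared[[tid]]
      molecules <- lapply(prepared, function(m) {
        if (identical(m$compound_id, tid)) {
          m$scaffold_map <- cbind(seq_len(nrow(m$atoms)), seq_len(nrow(m$atoms)))
          m$meta$scaffold_rmsd <- 0
          m
        } else align_to_template(m, template)
      })
      say("prep", "prepared and aligned %d structures onto %s",
          length(molecules), tid)
      records <- records[records$compound_id %in% names(molecules), ]
    }
  }
  if (is.null(molecules)) {
    stop_duotox("no structures available for field calculation; supply ",
                "structures= or a synthetic spec", class = "duotox_config_error")
  }

  # --- stage 2: descriptors --------------------------------------------------
  descriptors <- assemble_descriptors(molecules, config$fields)
  keep <- match(records$compound_id, descriptors$compound_ids)
  stopifnot(!anyNA(keep))
  say("fields", "descriptor matrix %d x %d", nrow(descriptors$X), ncol(descriptors$X))

  # --- stage 3: PLS + validation --------------------------------------------
  y <- records$composite
  report <- fit_qsar(descriptors, y, split = records$split,
                     max_components = config$pls$max_components,
                     criterion = config$pls$criterion)
  say("pls", "n=%d q2=%.3f R2=%.3f r2_pred=%s", report$n_components, report$q2,
      report$r2, ifelse(is.finite(report$r2_pred),
                        sprintf("%.3f", report$r2_pred), "NA"))

  contours <- extract_contours(report$model, descriptors,
                               favored_pct = config$pls$favored_pct,
                               disfavored_pct = config$pls$disfavored_pct)

  scrambling <- NULL
  if (isTRUE(config$pls$scramble)) {
    tr <- records$split == "train"
    scrambling <- progressive_scrambling(
      descriptors$X[tr, , drop = FALSE], y[tr], report$n_components,
      levels = config$pls$scramble_levels, seed = seeds[3L],
      n_replicates = config$pls$n_replicates)
    say("scramble", "Q2=%.3f cSDEP=%.3f slope=%.3f", scrambling$q2_scr,
        scrambling$csdep, scrambling$slope)
  }

  # --- stage 4: bundle -------------------------------------------------------
  staging <- paste0(config$out_dir, ".staging")
  dir.create(staging, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    c(qsar_report_to_list(report), list(seed = config$seed)),
    file.path(staging, "model_report.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(scrambling)) {
    jsonlite::write_json(
      list(q2_scr = scrambling$q2_scr, csdep = scrambling$csdep,
           slope = scrambling$slope, baseline_q2 = scrambling$baseline_q2,
           levels = scrambling$levels),
      file.path(staging, "scrambling_report.json"), auto_unbox = TRUE,
      digits = NA)
  }
  for (f in names(contours$fields)) {
    write_dx(contours$grid, contours$fields[[f]]$values,
             file.path(staging, sprintf("contour_%s.dx", f)))
  }
  utils::write.csv(records, file.path(staging, "composite_table.csv"),
                   row.names = FALSE)
  writeLines(log, file.path(staging, "run.log"))
  if (dir.exists(config$out_dir)) unlink(config$out_dir, recursive = TRUE)
  ok <- file.rename(staging, config$out_dir)
  if (!ok) stop_duotox("could not move bundle into place", class = "duotox_env_error")
  say("done", "bundle at %s", config$out_dir)

  structure(
    list(report = report, contours = contours, scrambling = scrambling,
         records = records, descriptors = descriptors, planted = planted,
         out_dir = config$out_dir, log = log),
    class = "pipeline_result"
  )
}
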