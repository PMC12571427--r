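## End-to-end pipeline: simulate/load -> phenotype (both CPs) ->
## prevalence -> TOST, with a machine-readable run manifest.

#' Assemble a pipeline configuration
#'
#' Exactly one input source must be given: `simulation` (arguments for
#' [sim_config()], or a ready `sim_config` object) to generate a synthetic
#' population, or `input_dir`, a directory of bundle tables readable by
#' [load_bundle()].
#'
#' @param simulation `NULL`, a list of [sim_config()] arguments, or a
#'   `sim_config`.
#' @param input_dir `NULL` or a directory path.
#' @param prevalence_year Integer year (default 2022).
#' @param cp2_mode CP 2 T2D rule mode (`"or_printed"` or `"ratio_only"`).
#' @param delta,alpha,convention TOST settings, see [tost_two_proportions()].
#' @param out_dir Output directory for stage artifacts.
#' @param seed Integer seed; overrides the simulation seed when generating.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, input_dir = NULL,
                            prevalence_year = 2022L,
                            cp2_mode = c("or_printed", "ratio_only"),
                            delta = 2.5, alpha = 0.05,
                            convention = c("analytic", "printed_table"),
                            out_dir = tempfile("phenoequiv_run_"),
                            seed = NULL) {
  if (is.null(simulation) == is.null(input_dir)) {
    stop("exactly one input source required: simulation or input_dir")
  }
  if (!is.null(simulation) && !inherits(simulation, "sim_config")) {
    simulation <- do.call(sim_config, as.list(simulation))
  }
  if (!is.null(simulation) && !is.null(seed)) simulation$seed <- as.integer(seed)
  structure(list(
    simulation = simulation, input_dir = input_dir,
    prevalence_year = as.integer(prevalence_year),
    cp2_mode = match.arg(cp2_mode),
    delta = as.numeric(delta), alpha = as.numeric(alpha),
    convention = match.arg(convention),
    out_dir = out_dir,
    seed = if (is.null(seed)) simulation$seed else as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `simulation` key holds [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

pipeline_stage <- function(name, report, expr) {
  report(sprintf("stage '%s' starting", name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full phenotype-equivalence pipeline
#'
#' Stages: acquire input (synthetic generation or table loading), classify
#' every patient under both phenotypes, build the two stratified prevalence
#' tables, and test per-stratum equivalence with TOST.  All artifacts are
#' written under `config$out_dir` (labels, prevalence tables, equivalence
#' table, and `manifest.json` echoing the configuration, seed, package
#' version and per-stage row counts).  The run is deterministic given the
#' seed and inputs; on failure the partially written output directory is
#' removed and the error names the failing stage.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage progress messages.
#' @return A list with `bundle`, `truth` (or `NULL`), `labels_cp1`,
#'   `labels_cp2`, `prevalence_cp1`, `prevalence_cp2`, `equivalence`, and
#'   `manifest`, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- if (quiet) function(...) invisible() else function(msg) message(msg)
  out_dir <- config$out_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cleanup <- function() {
    if (created) unlink(out_dir, recursive = TRUE)
  }
  ok <- FALSE
  on.exit(if (!ok) cleanup(), add = TRUE)

  input <- pipeline_stage("input", report, {
    if (!is.null(config$simulation)) {
      gen <- generate_population(config$simulation)
      write_bundle(gen$bundle, file.path(out_dir, "tables"))
      data.table::fwrite(gen$truth, file.path(out_dir, "truth.csv"))
      gen
    } else {
      list(bundle = load_bundle(config$input_dir), truth = NULL)
    }
  })
  bundle <- input$bundle
  truth <- input$truth
  report(sprintf("  input: %d patients, %d encounters",
                 nrow(bundle$patients), nrow(bundle$encounters)))

  year <- config$prevalence_year
  cp2c <- cp2_criteria(t2d_rule_mode = config$cp2_mode)
  labels_cp1 <- pipeline_stage("phenotype_cp1", report,
                               classify_cp1(bundle, year))
  labels_cp2 <- pipeline_stage("phenotype_cp2", report,
                               classify_cp2(bundle, year, criteria = cp2c))
  data.table::fwrite(labels_cp1, file.path(out_dir, "cp1_labels.csv"))
  data.table::fwrite(labels_cp2, file.path(out_dir, "cp2_labels.csv"))
  report(sprintf("  labels: cp1 %d t2d, cp2 %d t2d",
                 sum(labels_cp1$label == "t2d"), sum(labels_cp2$label == "t2d")))

  prev <- pipeline_stage("prevalence", report, {
    el1 <- eligible_patients(bundle, "cp1", year)
    el2 <- eligible_patients(bundle, "cp2", year,
                             min_encounters = cp2c$min_encounters)
    list(cp1 = prevalence_table(labels_cp1, el1, bundle$patients, year),
         cp2 = prevalence_table(labels_cp2, el2, bundle$patients, year))
  })
  data.table::fwrite(prev$cp1, file.path(out_dir, "cp1_prevalence.csv"))
  data.table::fwrite(prev$cp2, file.path(out_dir, "cp2_prevalence.csv"))

  equi <- pipeline_stage("tost", report,
                         equivalence_table(prev$cp1, prev$cp2,
                                           delta = config$delta,
                                           alpha = config$alpha,
                                           convention = config$convention))
  data.table::fwrite(equi, file.path(out_dir, "equivalence.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenoequiv")),
    r_version = R.version.string,
    seed = config$seed,
    prevalence_year = year,
    cp2_mode = config$cp2_mode,
    delta = config$delta, alpha = config$alpha,
    convention = config$convention,
    simulation = if (!is.null(config$simulation)) {
      c(config$simulation[setdiff(names(config$simulation), "stratum_mix")],
        list(stratum_mix = as.data.frame(config$simulation$stratum_mix)))
    },
    input_dir = config$input_dir,
    rows = list(
      patients = nrow(bundle$patients), encounters = nrow(bundle$encounters),
      diagnoses = nrow(bundle$diagnoses), labs = nrow(bundle$labs),
      medications = nrow(bundle$medications),
      cp1_t2d = sum(labels_cp1$label == "t2d"),
      cp2_t2d = sum(labels_cp2$label == "t2d"),
      strata = nrow(equi))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  ok <- TRUE
  report("pipeline complete")
  invisible(list(bundle = bundle, truth = truth,
                 labels_cp1 = labels_cp1, labels_cp2 = labels_cp2,
                 prevalence_cp1 = prev$cp1, prevalence_cp2 = prev$cp2,
                 equivalence = equi, manifest = manifest))
}
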