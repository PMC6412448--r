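# Pipeline configuration: nested defaults for every stage, strict
# validation (unknown keys rejected), YAML round-trip.

#' Build a full pipeline configuration
#'
#' Returns the nested configuration driving [run_bp_pipeline()], with
#' documented defaults for every stage: the simulator ([sim_config()]
#' fields), EMD settings, feature settings, model settings, and evaluation
#' thresholds. Any subset can be overridden; unknown keys are rejected.
#'
#' @param simulation named list overriding [sim_config()] arguments.
#' @param emd named list: `sd_threshold` (0.2), `max_imfs` (10),
#'   `beat_band_hz` (c(0.5, 12)).
#' @param features named list: `ai_convention`
#'   (`"systolic_over_dicrotic"`), `hr_bounds_bpm` (c(40, 180)),
#'   `min_beats` (3).
#' @param models named list: `algorithms` (c("rfr","gbr","abr")),
#'   `n_estimators` (100), `learning_rate` (0.1), `split_ratio` (0.8),
#'   `split_mode` ("record").
#' @param evaluation named list: `thresholds` (c(5, 10, 15)).
#' @param seed global seed; every stage seed is derived from it.
#' @param outdir optional output directory for [run_bp_pipeline()] artifacts.
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = list(), emd = list(),
                            features = list(), models = list(),
                            evaluation = list(), seed = 1L, outdir = NULL) {
  defaults <- list(
    simulation = as.list(unclass(sim_config())),
    emd = list(sd_threshold = 0.2, max_imfs = 10L, beat_band_hz = c(0.5, 12)),
    features = list(ai_convention = "systolic_over_dicrotic",
                    hr_bounds_bpm = c(40, 180), min_beats = 3L),
    models = list(algorithms = c("rfr", "gbr", "abr"), n_estimators = 100L,
                  learning_rate = 0.1, split_ratio = 0.8,
                  split_mode = "record"),
    evaluation = list(thresholds = c(5, 10, 15)),
    seed = 1L, outdir = NULL
  )
  merge_section <- function(section, override, path) {
    unknown <- setdiff(names(override), names(section))
    if (length(unknown))
      stop("unknown config key(s) under ", path, ": ",
           paste(unknown, collapse = ", "))
    section[names(override)] <- override
    section
  }
  cfg <- defaults
  cfg$simulation <- merge_section(defaults$simulation, simulation, "simulation")
  cfg$emd <- merge_section(defaults$emd, emd, "emd")
  cfg$features <- merge_section(defaults$features, features, "features")
  cfg$models <- merge_section(defaults$models, models, "models")
  cfg$evaluation <- merge_section(defaults$evaluation, evaluation, "evaluation")
  cfg$seed <- as.integer(seed)
  cfg$outdir <- outdir
  # re-derive the simulator seed from the global seed unless overridden
  if (is.null(simulation$seed)) cfg$simulation$seed <- cfg$seed
  class(cfg) <- "pipeline_config"
  do.call(sim_config, cfg$simulation)  # validates the simulation section
  stopifnot(cfg$models$split_mode %in% c("record", "subject"),
            cfg$models$split_ratio > 0, cfg$models$split_ratio < 1,
            all(cfg$models$algorithms %in% c("rfr", "gbr", "abr")))
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the [pipeline_config()] sections (flat key/value pairs
#' under `simulation`, `emd`, `features`, `models`, `evaluation`, plus
#' top-level `seed` and `outdir`). Unknown sections or keys are rejected.
#'
#' @param path YAML file path.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("simulation", "emd", "features", "models", "evaluation",
             "seed", "outdir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- raw[intersect(names(raw), known)]
  # unify scalars that YAML reads as length-1 lists
  for (s in c("simulation", "emd", "features", "models", "evaluation"))
    if (!is.null(args[[s]])) args[[s]] <- lapply(args[[s]], unlist)
  if (is.null(args$seed)) args$seed <- 1L
  do.call(pipeline_config, args)
}

# k deterministic per-stage seeds derived from one global seed
derive_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}
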