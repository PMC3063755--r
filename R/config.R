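# Structured run configuration (YAML) and deterministic run manifests.

CONFIG_SCHEMA <- list(
  coil = c("radius", "turns", "standoff", "center_offset"),
  pulse = c("V0", "R", "L", "C"),
  morphology = c("swc", "toy"),
  mechanisms = NULL,   # free-form tag -> overrides
  sim = c("dt", "t_stop", "record", "save_every", "pulse_delay", "v_init"),
  protocol = c("kind", "experiment", "overrides", "bounds", "resolution",
               "output")
)

#' Validate a run configuration
#'
#' Checks a configuration list (or YAML file) against the schema: known
#' blocks and keys only, quantities parseable (unit suffixes allowed) and
#' physical (positive R, L, C, radius, turns, standoff). Returns the
#' resolved configuration with all quantities converted to SI numerics.
#'
#' @param config named list or path to a YAML file.
#' @return the resolved configuration, invisibly classed `ms_run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  bad <- setdiff(names(config), names(CONFIG_SCHEMA))
  if (length(bad))
    stop("unknown config block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (blk in names(config)) {
    keys <- CONFIG_SCHEMA[[blk]]
    if (!is.null(keys)) {
      extra <- setdiff(names(config[[blk]]), keys)
      if (length(extra))
        stop("unknown key(s) in block '", blk, "': ",
             paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  q <- function(blk, key, default = NULL) {
    v <- config[[blk]][[key]]
    if (is.null(v)) default else parse_quantity(v)
  }
  for (key in c("V0", "R", "L", "C")) {
    v <- q("pulse", key)
    if (!is.null(v) && v <= 0 && !(key == "V0" && v == 0))
      stop("pulse.", key, " must be positive", call. = FALSE)
    config$pulse[[key]] <- v
  }
  for (key in c("radius", "standoff")) {
    v <- q("coil", key)
    if (!is.null(v) && v <= 0)
      stop("coil.", key, " must be positive", call. = FALSE)
    config$coil[[key]] <- v
  }
  if (!is.null(config$coil$center_offset))
    config$coil$center_offset <- parse_quantity(config$coil$center_offset)
  invisible(structure(config, class = "ms_run_config"))
}

#' Execute a validated run configuration
#'
#' Dispatches on `protocol$kind`: `"simulate"` (one [ms_run()], traces
#' written as delimited text), `"threshold"` ([find_magnetic_threshold()]),
#' `"experiment"` ([run_experiment()]) or `"field-export"`
#' ([export_field_grid()] + [write_field_grid()]). Results are written to
#' `protocol$output` (if set) together with a YAML manifest of the fully
#' resolved configuration, so any run is reproducible from its own header.
#'
#' @param config list / YAML path, validated by [validate_config()].
#' @return the protocol's result object.
#' @export
run_config <- function(config) {
  cfg <- validate_config(config)
  co <- if (!is.null(cfg$coil))
    coil(cfg$coil$radius, cfg$coil$turns %||% 30L, cfg$coil$standoff,
         cfg$coil$center_offset %||% c(0, 0)) else NULL
  pu <- if (!is.null(cfg$pulse))
    rlc_params(cfg$pulse$V0 %||% 0, cfg$pulse$R, cfg$pulse$L, cfg$pulse$C)
    else NULL
  neuron <- if (!is.null(cfg$morphology$swc)) load_swc(cfg$morphology$swc)
            else if (!is.null(cfg$morphology$toy)) build_toy(cfg$morphology$toy)
            else NULL
  mech_map <- default_mechanisms()
  for (tag in names(cfg$mechanisms)) {
    ov <- cfg$mechanisms[[tag]]
    mech_map[[tag]] <- do.call(mechanism, ov)
  }
  sim_args <- cfg$sim %||% list()
  sc <- do.call(sim_config, sim_args[!vapply(sim_args, is.null, logical(1))])
  kind <- cfg$protocol$kind %||% "simulate"
  result <- switch(kind,
    simulate = ms_run(neuron, co, pu, mech_map, sc),
    threshold = find_magnetic_threshold(
      neuron, co, pu, mech_map = mech_map, config = sc,
      resolution = cfg$protocol$resolution %||% 0.25),
    experiment = run_experiment(cfg$protocol$experiment,
                                cfg$protocol$overrides %||% list()),
    `field-export` = export_field_grid(
      co, parse_quantity(cfg$protocol$overrides$extent %||% "2cm"),
      parse_quantity(cfg$protocol$overrides$resolution %||% "0.05cm")),
    stop("unknown protocol kind: ", kind, call. = FALSE))
  out <- cfg$protocol$output
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(list(package = "magstim",
                          version = as.character(utils::packageVersion("magstim")),
                          config = unclass(cfg)),
                     file.path(out, "manifest.yaml"))
    if (inherits(result, "ms_sim")) write_sim(result, file.path(out, "traces.tsv"))
    if (is.data.frame(result))
      write.table(result, file.path(out, "results.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    if (inherits(result, "ms_field_grid")) write_field_grid(result, out)
    if (inherits(result, "ms_threshold"))
      writeLines(sprintf("threshold: %.4g %s", result$threshold, result$unit),
                 file.path(out, "threshold.txt"))
  }
  result
}
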