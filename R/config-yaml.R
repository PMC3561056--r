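#' Read a pipeline configuration from YAML
#'
#' A file-based front end to [run_config()] for runs on persisted inputs.
#' Recognised keys mirror the `run_config()` arguments (`stages`, `seed`,
#' `wells_path`, `traces_path`, `descriptors_path`, `predicted_edges_path`,
#' `control_condition`, `experiment_id`, `threshold_multiplier`,
#' `concentrations`, `screening_conc`, `hit_threshold`,
#' `counterscreen_threshold`, `out_dir`); `demo: true` with a `seed` returns
#' [demo_run_config()].  Unknown keys are an error so typos never pass
#' silently.
#'
#' @param path YAML file.
#' @return a `synlethnet_run_config`.
#' @export
read_run_config <- function(path) {
  check_that(file.exists(path), paste("config file does not exist:", path))
  raw <- yaml::read_yaml(path)
  if (isTRUE(raw$demo)) {
    return(demo_run_config(seed = raw$seed %||% 1L,
                           out_dir = raw$out_dir))
  }
  known <- c("stages", "seed", "wells_path", "traces_path",
             "descriptors_path", "predicted_edges_path", "control_condition",
             "experiment_id", "threshold_multiplier", "concentrations",
             "screening_conc", "hit_threshold", "counterscreen_threshold",
             "out_dir", "demo")
  unknown <- setdiff(names(raw), known)
  check_that(length(unknown) == 0,
             paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  args <- raw[intersect(names(raw), setdiff(known, c("demo", "predicted_edges_path")))]
  if (!is.null(raw$predicted_edges_path)) {
    args$predicted_edges <- raw$predicted_edges_path
  }
  do.call(run_config, args)
}
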