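# YAML round trip for rate constants and initial conditions.

#' Write rate constants and an initial state to a YAML config
#'
#' The file has two blocks, `parameters` (one key per rate constant) and
#' `initial_state` (one key per population). Values are written at
#' near-full double precision so a round trip reproduces them.
#'
#' @param params A [rate_parameters()] vector.
#' @param initial A [cell_state()] vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(params, initial, path) {
  params <- as_rate_parameters(params)
  initial <- as_cell_state(initial)
  cfg <- list(parameters = as.list(unclass(params)),
              initial_state = as.list(unclass(initial)))
  writeLines(yaml::as.yaml(cfg, precision = 15), path)
  invisible(path)
}

#' Read a model config written by [write_model_config()]
#'
#' @param path YAML file path.
#' @return A list with validated elements `params` ([rate_parameters()])
#'   and `initial` ([cell_state()]).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!all(c("parameters", "initial_state") %in% names(cfg))) {
    stop("config must contain 'parameters' and 'initial_state' blocks",
         call. = FALSE)
  }
  list(
    params = rate_parameters(unlist(cfg$parameters)),
    initial = cell_state(unlist(cfg$initial_state))
  )
}
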