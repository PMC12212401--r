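#' Read and write study descriptors
#'
#' A study descriptor is a small JSON file listing the injections (tracer,
#' injected activity in MBq, injection minute on the study clock, isotope
#' half-life in minutes), the body weight in kg and the region name of the
#' blood input function.  Together with a TAC CSV
#' (\code{\link{read_tac_csv}}) it fully specifies a measured study.
#'
#' @param file path to the JSON descriptor.
#' @param injections list of \code{\link{injection_event}}s.
#' @param body_weight kg.
#' @param input_region region name of the input-function curve in the TAC
#'   table.
#' @return \code{read_study_json} returns a list with \code{injections},
#'   \code{body_weight}, \code{input_region}.
#' @export
write_study_json <- function(injections, body_weight, input_region, file) {
  jsonlite::write_json(list(
    injections = lapply(injections, function(i)
      list(tracer = i$tracer, activity_MBq = i$activity_MBq,
           time_min = i$time_min, half_life_min = i$half_life_min)),
    body_weight_kg = body_weight, input_region = input_region),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_study_json
#' @export
read_study_json <- function(file) {
  x <- jsonlite::read_json(file)
  list(injections = lapply(x$injections, function(i)
    injection_event(i$tracer, i$activity_MBq, i$time_min,
                    i$half_life_min)),
    body_weight = x$body_weight_kg,
    input_region = x$input_region)
}

#' Load a measured dual-tracer study from files
#'
#' @param study_file JSON descriptor path (see
#'   \code{\link{write_study_json}}).
#' @param tac_file TAC CSV path (see \code{\link{read_tac_csv}}).
#' @return A \code{\link{dual_tracer_study}}.
#' @export
read_dual_tracer_study <- function(study_file, tac_file) {
  desc <- read_study_json(study_file)
  curves <- read_tac_csv(tac_file)
  if (!desc$input_region %in% names(curves))
    stop(sprintf("input region '%s' not found in TAC table",
                 desc$input_region))
  dual_tracer_study(desc$injections,
                    curves[[desc$input_region]],
                    curves[setdiff(names(curves), desc$input_region)],
                    desc$body_weight)
}
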