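#' Read a YAML run configuration
#'
#' Maps the optional \code{material}, \code{preprocess}, \code{solver} and
#' \code{load} sections of a YAML file onto the corresponding constructor
#' arguments, returning ready-to-use objects with package defaults filling
#' any omitted field.
#'
#' @param path YAML file, or NULL for all defaults.
#' @return list with \code{material} (\linkS4class{MaterialLaw}),
#'   \code{voi} (\linkS4class{VoiSpec}), \code{settings}
#'   (\linkS4class{SolverSettings}) and \code{load} (list with
#'   \code{totalStrain}, \code{nSubsteps}, \code{modes}).
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  build <- function(fun, args) do.call(fun, args[names(args) %in%
                                                  names(formals(fun))])
  list(
    material = build(materialLaw, cfg$material %||% list()),
    voi = build(voiSpec, cfg$preprocess %||% list()),
    settings = build(solverSettings, cfg$solver %||% list()),
    load = list(
      totalStrain = cfg$load$totalStrain %||% 0.001,
      nSubsteps = cfg$load$nSubsteps %||% 50L,
      modes = cfg$load$modes %||% c("compression", "x_shear", "y_shear")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
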