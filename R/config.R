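## run configuration: one human-editable YAML file covering the neuron
## parameter profiles, the wiring recipe and the integration settings.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default run configuration
#'
#' The full set of model constants as a nested list: \code{neuron$PKJ} and
#' \code{neuron$MLI} (the cell parameter profiles), \code{network} (the
#' wiring recipe, with probabilities derived from the anatomical
#' convergence/divergence targets) and \code{sim} (duration, dt, seed).
#'
#' @return a list of class "RunConfig".
#' @export
defaultRunConfig <- function() {
  cfg <- networkConfig()
  structure(list(
    neuron = .PARAM_DEFAULTS,
    network = list(
      nPkj = cfg@nPkj, mliPerPkj = cfg@mliPerPkj,
      lowerMliPerPkj = cfg@lowerMliPerPkj, pkjSpacingUm = cfg@pkjSpacingUm,
      mliAxonSpanPkjs = cfg@mliAxonSpanPkjs,
      pkjCollateralSpanPkjs = cfg@pkjCollateralSpanPkjs,
      pMliToPkj = cfg@pMliToPkj, pMliToMli = cfg@pMliToMli,
      pPkjToMli = cfg@pPkjToMli,
      wMax = as.list(cfg@wMax), seed = cfg@seed),
    sim = list(duration = 300e3, dt = 0.25, simSeed = 2L)),
    class = "RunConfig")
}

## Recursively reject keys that do not exist in the default skeleton.
.checkKeys <- function(given, skeleton, path = "") {
  if (!is.list(given)) return(invisible(NULL))
  bad <- setdiff(names(given), names(skeleton))
  if (length(bad))
    stop("unknown configuration key: ", path, bad[1], call. = FALSE)
  for (nm in names(given))
    if (is.list(skeleton[[nm]]))
      .checkKeys(given[[nm]], skeleton[[nm]], paste0(path, nm, "$"))
  invisible(NULL)
}

## Materialise the S4 objects from a RunConfig, running all validity checks.
.configObjects <- function(rc) {
  params <- lapply(c(PKJ = "PKJ", MLI = "MLI"), function(cls)
    do.call(neuronParams, c(list(cellClass = cls), rc$neuron[[cls]])))
  nw <- rc$network
  cfg <- networkConfig(nPkj = nw$nPkj, mliPerPkj = nw$mliPerPkj,
                       lowerMliPerPkj = nw$lowerMliPerPkj,
                       pkjSpacingUm = nw$pkjSpacingUm,
                       mliAxonSpanPkjs = nw$mliAxonSpanPkjs,
                       pkjCollateralSpanPkjs = nw$pkjCollateralSpanPkjs,
                       pMliToPkj = nw$pMliToPkj, pMliToMli = nw$pMliToMli,
                       pPkjToMli = nw$pPkjToMli,
                       wMax = unlist(nw$wMax), seed = nw$seed)
  settings <- simSettings(rc$sim$duration, dt = rc$sim$dt,
                          simSeed = rc$sim$simSeed)
  list(params = params, config = cfg, settings = settings)
}

#' Load / save a run configuration
#'
#' \code{loadConfig()} reads a YAML file, rejects unknown keys (naming the
#' offending key), fills unset fields from [defaultRunConfig()], and
#' validates every value by constructing the corresponding S4 objects. An
#' empty file yields the full defaults. \code{saveConfig()} writes a
#' RunConfig back to YAML with enough precision to round-trip exactly.
#'
#' @param path YAML file path.
#' @param rc a RunConfig list.
#' @return \code{loadConfig()} a validated RunConfig;
#'   \code{saveConfig()} the path, invisibly.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  given <- yaml::read_yaml(path)
  defaults <- defaultRunConfig()
  if (is.null(given)) given <- list()
  .checkKeys(given, defaults)
  rc <- modifyList(defaults, given)
  class(rc) <- "RunConfig"
  .configObjects(rc)  # validity checks; errors name the bad value
  rc
}

#' @rdname loadConfig
#' @export
saveConfig <- function(rc, path) {
  yaml::write_yaml(unclass(rc), path, precision = 17)
  invisible(path)
}
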