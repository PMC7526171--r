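#' Default model parameters
#'
#' Returns the full parameter set of the model: rate and binding constants of
#' the cdG module, the SpoT/(p)ppGpp module, the GTP/GMP interconversion and
#' the PTS-Ntr phosphorelay. Units are micromolar and minutes throughout;
#' enzyme abundances (DgcB, basal PDE) are on the scaled (relative immunoblot)
#' scale used for the sinusoid profiles.
#'
#' Fields:
#' \describe{
#'   \item{k_s_cdG, k_d_cdG}{scaled cdG synthesis / degradation rates (1/min)}
#'   \item{K1}{dissociation constant for cdG product inhibition of DGC (uM);
#'     inhibition is cooperative with Hill exponent 2 (two cdG molecules bind
#'     the I-site of the DGC dimer)}
#'   \item{Km1, Km2}{GTP affinity of DGC, cdG affinity of PDE (uM)}
#'   \item{DgcB, basalPDE}{constant parts of total DGC and PDE (scaled uM)}
#'   \item{k_s_ppGpp, k_d_ppGpp}{(p)ppGpp synthesis / degradation rates
#'     (uM/min)}
#'   \item{K2, K3, K_SpoT}{constants of the SpoT synthetase:hydrolase
#'     partition: NPr~P affinity, EIIA~P dissociation constant and the
#'     overall activity constant}
#'   \item{Km3, Km4}{GTP affinity of SpoT synthetase, (p)ppGpp affinity of
#'     SpoT hydrolase (uM)}
#'   \item{K4, eps}{glutamine inhibition of EI-Ntr autophosphorylation:
#'     half-saturation (uM) and residual activity fraction}
#'   \item{k_s_GTP, k_d_GTP}{GMP -> GTP and GTP -> GMP interconversion rates
#'     (1/min)}
#'   \item{EI_T, NPr_T, EIIA_T}{total PTS-Ntr enzyme levels (uM)}
#'   \item{k1, k_1}{EI autophosphorylation forward/back rates (1/min)}
#'   \item{k2, k3}{EI~P <-> NPr and NPr~P <-> EIIA phosphotransfer rates
#'     (1/(min uM)); forward and back rates are equal for each step}
#'   \item{Kd1, Kd2}{dissociation constants of the EI.PEP and EI~P.Pyr
#'     complexes (uM)}
#' }
#'
#' @return A named list of class `"cdgpp_params"`.
#' @examples
#' p <- default_params()
#' p$K1
#' @export
default_params <- function() {
  validate_params(structure(list(
    k_s_cdG   = 33.5,
    k_d_cdG   = 100,
    K1        = 0.5,
    Km1       = 1500,
    Km2       = 0.06,
    DgcB      = 0.7,
    basalPDE  = 0.2,
    k_s_ppGpp = 170,
    k_d_ppGpp = 160,
    K2        = 75,
    K3        = 10,
    K_SpoT    = 4,
    Km3       = 1000,
    Km4       = 2000,
    K4        = 75.63,
    eps       = 0.1,
    k_s_GTP   = 1500,
    k_d_GTP   = 100,
    EI_T      = 10,
    NPr_T     = 30,
    EIIA_T    = 30,
    k1        = 52.4,
    k_1       = 67.2,
    k2        = 1.2e4,
    k3        = 3.7e3,
    Kd1       = 350,
    Kd2       = 670
  ), class = "cdgpp_params"))
}

.param_names <- function() names(unclass(default_params()))

#' Validate a parameter set
#'
#' Checks that all parameters are present, strictly positive, and that the
#' glutamine residual activity `eps` lies in (0, 1].
#'
#' @param params A named list of parameters.
#' @return The validated parameter set (invisibly classed `"cdgpp_params"`).
#' @export
validate_params <- function(params) {
  wanted <- c("k_s_cdG", "k_d_cdG", "K1", "Km1", "Km2", "DgcB", "basalPDE",
              "k_s_ppGpp", "k_d_ppGpp", "K2", "K3", "K_SpoT", "Km3", "Km4",
              "K4", "eps", "k_s_GTP", "k_d_GTP", "EI_T", "NPr_T", "EIIA_T",
              "k1", "k_1", "k2", "k3", "Kd1", "Kd2")
  missing <- setdiff(wanted, names(params))
  if (length(missing) > 0L)
    stop("missing parameters: ", paste(missing, collapse = ", "))
  vals <- unlist(params[wanted])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all parameters must be finite and strictly positive")
  if (params$eps > 1)
    stop("eps must lie in (0, 1]")
  structure(params[wanted], class = "cdgpp_params")
}

#' Read or write a parameter set as flat JSON
#'
#' Parameter sets serialize to a flat JSON object keyed by the parameter
#' names of [default_params()]. The bundled file
#' `system.file("extdata", "params_default.json", package = "cdgpp")`
#' reproduces the default values exactly.
#'
#' @param path File path.
#' @param params A parameter set.
#' @return `read_params()` returns a validated parameter set;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_params(lapply(as.list(obj), as.numeric))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  params <- validate_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.cdgpp_params <- function(x, ...) {
  cat("Model parameter set (", length(x), " constants, uM / min units)\n",
      sep = "")
  print(unlist(unclass(x)))
  invisible(x)
}
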