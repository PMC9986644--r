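#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Canonical element order used throughout; the registry is open-ended in the
## sense that ReferenceSet/ToxicityTable may carry additional elements.
.pteElements <- c("As", "Cd", "Pb", "Cr", "Ni", "Cu")

## Registered land-use codes: park area, playground, market, brickfield,
## industrial area, petrol pump, metal workshop, bus stand, power station,
## residential area, waste dumping area.
.landUseCodes <- c("PA", "PG", "M", "BF", "IA", "PP", "MW", "BS", "PS",
                   "RA", "WDA")

.riskRoutes <- c("ingestion", "dermal", "inhalation")

#' Registered land-use codes
#'
#' The eleven land-use classes the pipeline recognises: park area (PA),
#' playground (PG), market (M), brickfield (BF), industrial area (IA),
#' petrol pump (PP), metal workshop (MW), bus stand (BS), power station (PS),
#' residential area (RA) and waste dumping area (WDA).
#'
#' @return Character vector of the eleven codes.
#' @export
#' @examples
#' landUseCodes()
landUseCodes <- function() .landUseCodes

#' Canonical element set
#'
#' The six potentially toxic elements the shipped reference tables cover,
#' in the order used by all reports.
#'
#' @return Character vector `c("As","Cd","Pb","Cr","Ni","Cu")`.
#' @export
pteElements <- function() .pteElements

#' Exposure routes
#'
#' @return Character vector of the three assessed exposure routes.
#' @export
riskRoutes <- function() .riskRoutes

#' SoilSamples: per-sample element concentrations
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' assay `"conc"` (elements x samples, mg/kg dry weight), per-sample
#' `land_use` in `colData`, optional per-element method detection limits
#' (`mdl` in `rowData`) and an optional logical assay `"below_detection"`
#' flagging censored cells. Iron, when measured, is carried as an ordinary
#' `"Fe"` row and excluded from index computations by the accessors.
#'
#' @section Validity:
#' All concentrations must be finite and non-negative; every `land_use` must
#' be one of [landUseCodes()]; any cell flagged below detection must have a
#' positive MDL for its element.
#'
#' @seealso [SoilSamples()] for the constructor, [readSampleTable()] for CSV
#'   input.
#' @export
setClass("SoilSamples", contains = "SummarizedExperiment")

setValidity("SoilSamples", function(object) {
  msg <- character(0)
  if (!"conc" %in% SummarizedExperiment::assayNames(object))
    return("assay 'conc' is required")
  conc <- SummarizedExperiment::assay(object, "conc")
  if (!is.numeric(conc))
    msg <- c(msg, "'conc' assay must be numeric")
  bad <- which(!is.finite(conc) | conc < 0)
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(conc))
    msg <- c(msg, sprintf(
      "negative or non-finite concentration for element '%s', sample '%s'",
      rownames(conc)[idx[1]], colnames(conc)[idx[2]]))
  }
  if (!"land_use" %in% colnames(SummarizedExperiment::colData(object))) {
    msg <- c(msg, "colData must contain 'land_use'")
  } else {
    lu <- as.character(object$land_use)
    unknown <- which(!lu %in% .landUseCodes)
    if (length(unknown))
      msg <- c(msg, sprintf("unknown land-use code '%s' for sample '%s'",
                            lu[unknown[1]], colnames(object)[unknown[1]]))
  }
  if ("below_detection" %in% SummarizedExperiment::assayNames(object)) {
    bd <- SummarizedExperiment::assay(object, "below_detection")
    if (!is.logical(bd))
      msg <- c(msg, "'below_detection' assay must be logical")
    mdl <- SummarizedExperiment::rowData(object)$mdl
    if (any(bd, na.rm = TRUE)) {
      if (is.null(mdl)) {
        msg <- c(msg, "below-detection flags require an 'mdl' rowData column")
      } else {
        need <- rowSums(bd, na.rm = TRUE) > 0
        if (any(need & (is.na(mdl) | mdl <= 0)))
          msg <- c(msg, sprintf(
            "element '%s' has below-detection cells but no positive MDL",
            rownames(object)[which(need & (is.na(mdl) | mdl <= 0))[1]]))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' ReferenceSet: background, toxicity-response and regulatory values
#'
#' Per-element geochemical background concentrations (mg/kg), Hakanson
#' toxic-response factors (dimensionless), nominal method detection limits
#' (mg/kg) and a matrix of regulatory screening standards (rows = standard
#' name, e.g. DSQS/CSQS/TRV/ASQS; columns = element, mg/kg). The iron
#' background used by the enrichment factor is optional (`NA` when unknown).
#'
#' @seealso [defaultReferences()] for the shipped study-area values.
#' @export
setClass("ReferenceSet",
  representation(background = "numeric", fe_background = "numeric",
                 toxic_response = "numeric", mdl = "numeric",
                 standards = "matrix"))

setValidity("ReferenceSet", function(object) {
  msg <- character(0)
  bg <- object@background
  if (is.null(names(bg)) || any(!nzchar(names(bg))))
    msg <- c(msg, "background values must be named by element")
  if (any(!is.finite(bg) | bg <= 0))
    msg <- c(msg, sprintf("background must be strictly positive (element '%s')",
                          names(bg)[which(!is.finite(bg) | bg <= 0)[1]]))
  tr <- object@toxic_response
  if (length(tr) && any(!is.finite(tr) | tr <= 0))
    msg <- c(msg, "toxic-response factors must be strictly positive")
  if (length(object@fe_background) != 1)
    msg <- c(msg, "fe_background must be a single value (possibly NA)")
  if (length(object@mdl) && any(object@mdl <= 0, na.rm = TRUE))
    msg <- c(msg, "MDL values must be positive")
  if (length(msg)) msg else TRUE
})

#' ExposureProfile: receptor-specific exposure parameters
#'
#' The USEPA point-estimate exposure parameters for one receptor class.
#' Units follow the conventional exposure model: body weight kg; exposure
#' frequency days/year; exposure duration years; soil ingestion rate mg/day;
#' inhalation rate m3/day; exposed skin area cm2; soil-to-skin adherence
#' mg/cm2; dermal absorption and dermal exposure ratio dimensionless;
#' particulate emission factor m3/kg; units conversion kg/mg. Averaging
#' times are derived: 365 x 70 days for carcinogens, 365 x ED days for
#' non-carcinogens.
#'
#' @seealso [exposureProfile()] for the shipped child/adult defaults.
#' @export
setClass("ExposureProfile",
  representation(receptor = "character", body_weight = "numeric",
                 exposure_frequency = "numeric", exposure_duration = "numeric",
                 ingestion_rate = "numeric", inhalation_rate = "numeric",
                 skin_area = "numeric", adherence_factor = "numeric",
                 dermal_absorption = "numeric", dermal_exposure_ratio = "numeric",
                 particulate_emission_factor = "numeric",
                 conversion_factor = "numeric"))

setValidity("ExposureProfile", function(object) {
  nums <- c(object@body_weight, object@exposure_frequency,
            object@exposure_duration, object@ingestion_rate,
            object@inhalation_rate, object@skin_area, object@adherence_factor,
            object@dermal_absorption, object@dermal_exposure_ratio,
            object@particulate_emission_factor, object@conversion_factor)
  if (any(!is.finite(nums) | nums <= 0))
    return("all exposure parameters must be positive and finite")
  if (object@exposure_frequency > 366)
    return("exposure frequency cannot exceed 366 days/year")
  TRUE
})

#' ToxicityTable: route-specific reference doses and slope factors
#'
#' Reference doses (RfD, mg/kg/day) and cancer slope factors (CSF,
#' (mg/kg/day)^-1) per element and route. An `NA` entry means the pair is
#' *not assessed* -- it is never treated as zero. When only an oral
#' (ingestion) RfD is available the dermal and inhalation routes may fall
#' back to it (flagged in reports).
#'
#' @seealso [defaultToxicity()], [toxicityTable()].
#' @export
setClass("ToxicityTable",
  representation(rfd = "matrix", csf = "matrix"))

setValidity("ToxicityTable", function(object) {
  msg <- character(0)
  for (slotname in c("rfd", "csf")) {
    m <- slot(object, slotname)
    if (!identical(colnames(m), .riskRoutes))
      msg <- c(msg, sprintf("'%s' columns must be %s", slotname,
                            paste(.riskRoutes, collapse = "/")))
    if (any(m <= 0, na.rm = TRUE))
      msg <- c(msg, sprintf("defined '%s' entries must be positive", slotname))
  }
  if (length(msg)) msg else TRUE
})

#' PMFSolution: one converged positive-matrix-factorization run
#'
#' Holds the factor profiles (factors x elements, concentration units after
#' scale normalisation is absorbed into the contributions), non-negative
#' sample contributions (samples x factors), residuals (defined exactly as
#' X - G F), the uncertainty matrix used for weighting, the objective values
#' Q(true) and Q(robust), a per-iteration Q trace for the winning run, the
#' per-element coefficient of determination, and the all-run bookkeeping
#' table.
#'
#' @seealso [fitPMF()].
#' @export
setClass("PMFSolution",
  representation(n_factors = "integer", profiles = "matrix",
                 contributions = "matrix", residuals = "matrix",
                 alpha = "matrix", q_true = "numeric", q_robust = "numeric",
                 q_trace = "numeric", run_seed = "integer",
                 converged = "logical", r2 = "numeric", runs = "data.frame"))

setValidity("PMFSolution", function(object) {
  msg <- character(0)
  if (any(object@profiles < 0) || any(object@contributions < 0))
    msg <- c(msg, "profiles and contributions must be non-negative")
  if (any(object@alpha <= 0))
    msg <- c(msg, "uncertainties must be strictly positive")
  if (length(msg)) msg else TRUE
})
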