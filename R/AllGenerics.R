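#' @include AllClasses.R
NULL

#' @rdname SoilSamples-class
#' @param x,object a `SoilSamples` (or other class) instance
#' @export
setGeneric("concMatrix", function(x) standardGeneric("concMatrix"))

#' @rdname SoilSamples-class
#' @export
setGeneric("landUse", function(x) standardGeneric("landUse"))

#' @rdname SoilSamples-class
#' @export
setGeneric("belowDetection", function(x) standardGeneric("belowDetection"))

#' @rdname SoilSamples-class
#' @export
setGeneric("detectionLimits", function(x) standardGeneric("detectionLimits"))

#' @rdname SoilSamples-class
#' @export
setGeneric("feConc", function(x) standardGeneric("feConc"))

#' @rdname ReferenceSet-class
#' @param x a `ReferenceSet`
#' @export
setGeneric("background", function(x) standardGeneric("background"))

#' @rdname ReferenceSet-class
#' @export
setGeneric("toxicResponse", function(x) standardGeneric("toxicResponse"))

#' @rdname ReferenceSet-class
#' @export
setGeneric("standards", function(x) standardGeneric("standards"))

#' @rdname ReferenceSet-class
#' @export
setGeneric("feBackground", function(x) standardGeneric("feBackground"))

#' @rdname PMFSolution-class
#' @param x a `PMFSolution`
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))

#' @rdname PMFSolution-class
#' @export
setGeneric("contributions", function(x) standardGeneric("contributions"))

#' @rdname PMFSolution-class
#' @export
setGeneric("qTrue", function(x) standardGeneric("qTrue"))

#' @rdname PMFSolution-class
#' @export
setGeneric("qRobust", function(x) standardGeneric("qRobust"))

#' @rdname PMFSolution-class
#' @export
setGeneric("scaledResiduals", function(x) standardGeneric("scaledResiduals"))

#' @rdname PMFSolution-class
#' @export
setGeneric("elementR2", function(x) standardGeneric("elementR2"))

#' @rdname PMFSolution-class
#' @export
setGeneric("runTable", function(x) standardGeneric("runTable"))

#' Summarise samples by land-use site
#'
#' One row per (land-use, element) with the sample count, mean, sample
#' (n-1) standard deviation, minimum and maximum concentration. The SD of a
#' single-sample site is reported as `NA`.
#'
#' @param x a [SoilSamples] object
#' @return `data.frame` with columns `land_use`, `n`, `element`, `mean`,
#'   `sd`, `min`, `max`.
#' @export
setGeneric("summarizeBySite", function(x) standardGeneric("summarizeBySite"))

#' Per-site pollution indices
#'
#' Computes the contamination factor per element, the degree of
#' contamination, the geoaccumulation index per element and the pollution
#' load index for each land-use site, together with category labels.
#' Site values are computed from site-mean concentrations (the default
#' chaining of concentration summaries into index tables).
#'
#' @param x a [SoilSamples] object or a site-summary `data.frame` as
#'   returned by [summarizeBySite()]
#' @param refs a [ReferenceSet]
#' @param cdScheme scheme name for the degree-of-contamination label
#'   (`"cd_inferred"` reproduces the study-area labels; `"cd_hakanson"` is
#'   the classical scale)
#' @param ... passed between methods
#' @return `data.frame`, one row per site: `cf_<el>` columns, `c_d`,
#'   `igeo_<el>` columns, `pli`, `c_d_label`, `pli_label`.
#' @export
setGeneric("siteIndices", function(x, refs, ...) standardGeneric("siteIndices"))

#' Per-site Hakanson ecological risk
#'
#' Per-element ecological risk factors E_r = T_r x CF and their site sum
#' PERI, with category labels.
#'
#' @param x a [SoilSamples] object or a site-summary `data.frame`
#' @param refs a [ReferenceSet]
#' @param periScheme scheme name for the PERI label (`"peri_inferred"` or
#'   `"peri_hakanson"`)
#' @param ... passed between methods
#' @return `data.frame`, one row per site: `er_<el>` columns, `peri`,
#'   `risk_level`, plus per-element `er_<el>_label` columns.
#' @export
setGeneric("siteEcoRisk", function(x, refs, ...) standardGeneric("siteEcoRisk"))
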