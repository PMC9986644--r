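#' @include AllGenerics.R
NULL

#' Per-element ecological risk factor
#'
#' Hakanson's E_r = T_r x CF: the contamination factor weighted by the
#' element's biological toxic-response factor (Cd 30 dominates the shipped
#' set; As 10, Ni 6, Pb 5, Cu 5, Cr 2).
#'
#' @param cf contamination factor(s), >= 0
#' @param toxic_response toxic-response factor(s), > 0
#' @return dimensionless ecological risk factor(s)
#' @export
#' @examples
#' ecologicalRiskFactor(0.85 / 0.30, 30)   # 85, Cd in a park-area soil
ecologicalRiskFactor <- function(cf, toxic_response) {
  if (any(cf < 0)) stop("contamination factors must be non-negative")
  if (any(!is.finite(toxic_response) | toxic_response <= 0))
    stop("toxic-response factors must be strictly positive")
  toxic_response * cf
}

#' Potential ecological risk index
#'
#' Site-level PERI: the sum of the per-element ecological risk factors.
#'
#' @param er numeric vector of ecological risk factors (non-empty)
#' @return dimensionless PERI
#' @export
potentialEcologicalRisk <- function(er) {
  if (!length(er)) stop("at least one ecological risk factor is required")
  sum(er)
}

#' Classify an ecological risk value
#'
#' Convenience wrapper around [classifyIndex()] with the ecological-risk
#' schemes: `er_hakanson` (per-element, 40/80/160/320 cutoffs),
#' `peri_hakanson` (150/300/600) and `peri_inferred` (cutoffs at 150 and
#' 200, reconstructed from the study-area labels which place sites in the
#' 150--165 band at "Considerable" and 283 at "Very high").
#'
#' @param value numeric vector of E_r or PERI values
#' @param scheme scheme name, default `"peri_inferred"`
#' @return character vector of labels
#' @export
classifyEcoRisk <- function(value, scheme = "peri_inferred") {
  classifyIndex(value, scheme)
}

#' @rdname siteEcoRisk
#' @export
setMethod("siteEcoRisk", signature(x = "data.frame", refs = "ReferenceSet"),
  function(x, refs, periScheme = "peri_inferred", ...) {
    bg <- background(refs)
    tr <- toxicResponse(refs)
    elements <- intersect(.pteElements, intersect(names(bg), names(tr)))
    elements <- intersect(elements, unique(x$element))
    means <- .siteMeansWide(x, elements)
    cf <- sweep(means, 2, bg[elements], `/`)
    er <- sweep(cf, 2, tr[elements], `*`)
    peri <- rowSums(er)
    out <- data.frame(land_use = rownames(means), stringsAsFactors = FALSE)
    for (el in elements) out[[paste0("er_", el)]] <- er[, el]
    out$peri <- peri
    out$risk_level <- classifyEcoRisk(peri, periScheme)
    for (el in elements)
      out[[paste0("er_", el, "_label")]] <- classifyIndex(er[, el], "er_hakanson")
    rownames(out) <- NULL
    out
  })

#' @rdname siteEcoRisk
#' @export
setMethod("siteEcoRisk", signature(x = "SoilSamples", refs = "ReferenceSet"),
  function(x, refs, periScheme = "peri_inferred", ...) {
    siteEcoRisk(summarizeBySite(x), refs, periScheme = periScheme, ...)
  })
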