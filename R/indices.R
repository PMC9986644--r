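#' @include AllGenerics.R
NULL

#' Contamination factor
#'
#' Ratio of a measured concentration to the geochemical background of the
#' same element, CF = C / B. Vectorised over elements.
#'
#' @param conc concentration(s), mg/kg (>= 0)
#' @param background background concentration(s), mg/kg (> 0)
#' @return dimensionless contamination factor(s)
#' @export
#' @examples
#' contaminationFactor(0.85, 0.30)   # 2.83, Cd in a park-area soil
contaminationFactor <- function(conc, background) {
  if (any(!is.finite(background) | background <= 0))
    stop("background concentrations must be strictly positive")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  conc / background
}

#' Degree of contamination
#'
#' Sum of the per-element contamination factors at a site.
#'
#' @param cf numeric vector of contamination factors (non-empty)
#' @return dimensionless degree of contamination
#' @export
degreeOfContamination <- function(cf) {
  if (!length(cf)) stop("at least one contamination factor is required")
  sum(cf)
}

#' Enrichment factor
#'
#' Double-normalised contamination: the sample's element-to-iron ratio over
#' the background element-to-iron ratio, EF = (C/Fe)_sample /
#' (B/Fe)_background. Iron serves as the conservative crustal normaliser.
#'
#' @param conc element concentration in the sample, mg/kg
#' @param fe_sample iron concentration in the sample, mg/kg (> 0)
#' @param background element background, mg/kg (> 0)
#' @param fe_background iron background, mg/kg (> 0)
#' @return dimensionless enrichment factor
#' @export
enrichmentFactor <- function(conc, fe_sample, background, fe_background) {
  norms <- c(fe_sample, background, fe_background)
  if (any(!is.finite(norms) | norms <= 0))
    stop("iron and background normalisers must be strictly positive")
  (conc / fe_sample) / (background / fe_background)
}

#' Geoaccumulation index
#'
#' Muller's index, Igeo = log2( C / (1.5 B) ); the 1.5 factor absorbs
#' natural lithogenic fluctuation around the background.
#'
#' @param conc concentration, mg/kg (> 0)
#' @param background background concentration, mg/kg (> 0)
#' @param zero how to treat a zero concentration: `"error"` (default; real
#'   soils are never exactly zero) or `"neginf"` for a -Inf sentinel
#' @return dimensionless geoaccumulation index
#' @export
#' @examples
#' geoaccumulationIndex(8.56, 4.90)   # 0.22, As in a park-area soil
geoaccumulationIndex <- function(conc, background, zero = c("error", "neginf")) {
  zero <- match.arg(zero)
  if (any(!is.finite(background) | background <= 0))
    stop("background concentrations must be strictly positive")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (any(conc == 0) && zero == "error")
    stop("zero concentration: Igeo undefined (set zero = 'neginf' to allow)")
  log2(conc / (1.5 * background))
}

#' Pollution load index
#'
#' Geometric mean (n-th root of the product) of the per-element
#' contamination factors; PLI > 1 flags deteriorating soil quality.
#'
#' @param cf numeric vector of contamination factors (all > 0)
#' @return dimensionless pollution load index
#' @export
#' @examples
#' pollutionLoadIndex(c(2, 8))   # 4
pollutionLoadIndex <- function(cf) {
  if (!length(cf)) stop("at least one contamination factor is required")
  if (any(!is.finite(cf) | cf <= 0))
    stop("all contamination factors must be strictly positive")
  exp(mean(log(cf)))
}

## ---------------------------------------------------------------------------
## site-level report

.siteMeansWide <- function(summary, elements) {
  sites <- intersect(.landUseCodes, unique(summary$land_use))
  m <- matrix(NA_real_, length(sites), length(elements),
              dimnames = list(sites, elements))
  for (i in seq_len(nrow(summary))) {
    if (summary$element[i] %in% elements)
      m[summary$land_use[i], summary$element[i]] <- summary$mean[i]
  }
  if (anyNA(m))
    stop("site summary is missing a (site, element) mean")
  m
}

#' @rdname siteIndices
#' @export
setMethod("siteIndices", signature(x = "data.frame", refs = "ReferenceSet"),
  function(x, refs, cdScheme = "cd_inferred", ...) {
    bg <- background(refs)
    elements <- intersect(.pteElements, names(bg))
    elements <- intersect(elements, unique(x$element))
    means <- .siteMeansWide(x, elements)
    cf <- sweep(means, 2, bg[elements], `/`)
    igeo <- log2(sweep(means, 2, 1.5 * bg[elements], `/`))
    c_d <- rowSums(cf)
    pli <- apply(cf, 1, pollutionLoadIndex)
    out <- data.frame(land_use = rownames(means), stringsAsFactors = FALSE)
    for (el in elements) out[[paste0("cf_", el)]] <- cf[, el]
    out$c_d <- c_d
    for (el in elements) out[[paste0("igeo_", el)]] <- igeo[, el]
    out$pli <- pli
    out$c_d_label <- classifyIndex(c_d, cdScheme)
    out$pli_label <- classifyIndex(pli, "pli_tomlinson")
    rownames(out) <- NULL
    out
  })

#' @rdname siteIndices
#' @export
setMethod("siteIndices", signature(x = "SoilSamples", refs = "ReferenceSet"),
  function(x, refs, cdScheme = "cd_inferred", ...) {
    siteIndices(summarizeBySite(x), refs, cdScheme = cdScheme, ...)
  })
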