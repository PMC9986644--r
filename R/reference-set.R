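#' @include AllGenerics.R
NULL

#' Construct a ReferenceSet
#'
#' @param background named numeric, geochemical background per element (mg/kg)
#' @param toxic_response named numeric, Hakanson toxic-response factors
#' @param standards numeric matrix, rows = standard names, cols = elements
#'   (mg/kg); may be a 0-row matrix
#' @param fe_background iron background concentration (mg/kg) or `NA`
#' @param mdl named numeric, nominal method detection limits (mg/kg)
#' @return a validated [ReferenceSet-class] object
#' @export
#' @examples
#' referenceSet(background = c(As = 4.9, Cd = 0.3),
#'              toxic_response = c(As = 10, Cd = 30))
referenceSet <- function(background, toxic_response = numeric(0),
                         standards = matrix(numeric(0), nrow = 0,
                                            ncol = length(background),
                                            dimnames = list(NULL, names(background))),
                         fe_background = NA_real_, mdl = numeric(0)) {
  new("ReferenceSet", background = background,
      toxic_response = toxic_response, standards = as.matrix(standards),
      fe_background = as.numeric(fe_background), mdl = mdl)
}

#' Shipped study-area reference values
#'
#' Reads the packaged reference table: pre-industrial background
#' concentrations for the Jashore study area, Hakanson toxic-response
#' factors (As 10, Cd 30, Pb 5, Cr 2, Ni 6, Cu 5), nominal instrument
#' detection limits, and four regulatory screening standards (Dutch DSQS,
#' Canadian CSQS, toxicity reference value TRV, Australian ASQS). The iron
#' background is not part of the shipped table and is `NA`.
#'
#' @return a [ReferenceSet-class] object
#' @export
#' @examples
#' refs <- defaultReferences()
#' background(refs)
defaultReferences <- function() {
  path <- system.file("extdata", "references.csv", package = "soilPTE",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  std_names <- setdiff(colnames(tab),
                       c("element", "background", "toxic_response", "mdl"))
  std <- t(as.matrix(tab[, std_names, drop = FALSE]))
  colnames(std) <- tab$element
  referenceSet(
    background = stats::setNames(tab$background, tab$element),
    toxic_response = stats::setNames(tab$toxic_response, tab$element),
    standards = std,
    mdl = stats::setNames(tab$mdl, tab$element))
}

#' @rdname ReferenceSet-class
#' @export
setMethod("background", "ReferenceSet", function(x) x@background)

#' @rdname ReferenceSet-class
#' @export
setMethod("toxicResponse", "ReferenceSet", function(x) x@toxic_response)

#' @rdname ReferenceSet-class
#' @export
setMethod("standards", "ReferenceSet", function(x) x@standards)

#' @rdname ReferenceSet-class
#' @export
setMethod("feBackground", "ReferenceSet", function(x) x@fe_background)

#' @rdname ReferenceSet-class
#' @export
setMethod("detectionLimits", "ReferenceSet", function(x) x@mdl)

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet for", length(object@background), "elements:",
      paste(names(object@background), collapse = ", "), "\n")
  cat("  standards:", if (nrow(object@standards))
    paste(rownames(object@standards), collapse = ", ") else "none", "\n")
  cat("  Fe background:", object@fe_background, "\n")
  invisible(NULL)
})
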