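#' @include AllGenerics.R
NULL

.schemeCache <- new.env(parent = emptyenv())

#' Classification schemes for pollution and risk indices
#'
#' Category bins are data, not code: the package ships the classical scales
#' (Hakanson contamination/risk classes, the Muller geoaccumulation scale,
#' the Tomlinson pollution-load threshold, a standard enrichment-factor
#' scale) plus two *inferred* schemes (`cd_inferred`, `peri_inferred`) whose
#' cutoffs were reconstructed from the study-area category labels, which are
#' inconsistent with the classical cutoffs. Bins are lower-inclusive,
#' `[lower, upper)`, and jointly cover the whole real line.
#'
#' @param name scheme name; one of the names in the shipped scheme table
#' @return `data.frame` with columns `lower`, `upper`, `label`
#' @export
#' @examples
#' indexScheme("cd_inferred")
indexScheme <- function(name) {
  if (is.null(.schemeCache$tab)) {
    path <- system.file("extdata", "schemes.csv", package = "soilPTE",
                        mustWork = TRUE)
    .schemeCache$tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  tab <- .schemeCache$tab[.schemeCache$tab$scheme == name, , drop = FALSE]
  if (!nrow(tab))
    stop(sprintf("unknown classification scheme '%s'", name))
  tab[order(tab$lower), c("lower", "upper", "label")]
}

#' Names of the shipped classification schemes
#' @return character vector
#' @export
schemeNames <- function() {
  indexScheme("cf_hakanson")  # populate cache
  unique(.schemeCache$tab$scheme)
}

#' Classify an index value
#'
#' Maps values onto the ordered, non-overlapping, lower-inclusive bins of a
#' classification scheme: a value on a bin boundary belongs to the upper
#' bin.
#'
#' @param value numeric vector of index values
#' @param scheme a scheme name (see [schemeNames()]) or a `data.frame` with
#'   `lower`, `upper`, `label` columns
#' @return character vector of labels
#' @export
#' @examples
#' classifyIndex(c(4.42, 7.03, 20.16), "cd_inferred")
classifyIndex <- function(value, scheme) {
  if (is.character(scheme)) scheme <- indexScheme(scheme)
  stopifnot(all(c("lower", "upper", "label") %in% colnames(scheme)))
  scheme <- scheme[order(scheme$lower), , drop = FALSE]
  if (any(scheme$lower[-1] != scheme$upper[-nrow(scheme)]))
    stop("scheme bins must be contiguous and non-overlapping")
  idx <- findInterval(value, c(scheme$lower, Inf), left.open = FALSE)
  if (any(idx < 1 | idx > nrow(scheme), na.rm = TRUE))
    stop("value outside all scheme bins")
  out <- scheme$label[idx]
  out[is.na(value)] <- NA_character_
  out
}
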