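#' @include AllGenerics.R
NULL

#' Construct a SoilSamples object
#'
#' @param conc numeric matrix of concentrations (mg/kg dry weight), elements
#'   in rows and samples in columns, with dimnames; or a samples-in-rows
#'   matrix which is transposed when `elementsInRows = FALSE`
#' @param land_use character vector of land-use codes, one per sample
#'   (case-insensitive on input, stored upper-case; see [landUseCodes()])
#' @param below_detection optional logical matrix, same shape as `conc`,
#'   flagging censored cells
#' @param mdl optional named numeric of per-element method detection limits
#' @param elementsInRows does `conc` already have elements in rows?
#' @return a validated [SoilSamples-class] object
#' @export
#' @examples
#' conc <- matrix(c(3.32, 8.46, 13.9, 0.7, 0.85, 1.05), nrow = 2,
#'                byrow = TRUE, dimnames = list(c("As", "Cd"),
#'                                              paste0("s", 1:3)))
#' SoilSamples(conc, land_use = c("PA", "PA", "PA"))
SoilSamples <- function(conc, land_use, below_detection = NULL, mdl = NULL,
                        elementsInRows = TRUE) {
  conc <- as.matrix(conc)
  if (!elementsInRows) conc <- t(conc)
  if (is.null(rownames(conc)))
    stop("'conc' must carry element names")
  if (is.null(colnames(conc)))
    colnames(conc) <- paste0("S", seq_len(ncol(conc)))
  land_use <- toupper(as.character(land_use))
  if (length(land_use) != ncol(conc))
    stop("'land_use' must have one code per sample")
  assays <- list(conc = conc)
  if (!is.null(below_detection)) {
    below_detection <- as.matrix(below_detection)
    dimnames(below_detection) <- dimnames(conc)
    assays$below_detection <- below_detection
  }
  rd <- S4Vectors::DataFrame(row.names = rownames(conc))
  if (!is.null(mdl))
    rd$mdl <- unname(mdl[rownames(conc)])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd,
    colData = S4Vectors::DataFrame(land_use = land_use,
                                   row.names = colnames(conc)))
  methods::new("SoilSamples", se)
}

#' @rdname SoilSamples-class
#' @export
setMethod("concMatrix", "SoilSamples", function(x)
  SummarizedExperiment::assay(x, "conc"))

#' @rdname SoilSamples-class
#' @export
setMethod("landUse", "SoilSamples", function(x) as.character(x$land_use))

#' @rdname SoilSamples-class
#' @export
setMethod("belowDetection", "SoilSamples", function(x) {
  if ("below_detection" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "below_detection")
  else
    matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
})

#' @rdname SoilSamples-class
#' @export
setMethod("detectionLimits", "SoilSamples", function(x) {
  mdl <- SummarizedExperiment::rowData(x)$mdl
  if (is.null(mdl)) return(stats::setNames(rep(NA_real_, nrow(x)), rownames(x)))
  stats::setNames(as.numeric(mdl), rownames(x))
})

#' @rdname SoilSamples-class
#' @export
setMethod("feConc", "SoilSamples", function(x) {
  if (!"Fe" %in% rownames(x)) return(NULL)
  concMatrix(x)["Fe", ]
})

setMethod("show", "SoilSamples", function(object) {
  lu <- table(landUse(object))
  cat("SoilSamples:", ncol(object), "samples x", nrow(object), "elements (",
      paste(rownames(object), collapse = ", "), ")\n")
  cat("  land uses:",
      paste(sprintf("%s(%d)", names(lu), lu), collapse = " "), "\n")
  nbd <- sum(belowDetection(object))
  if (nbd) cat("  below-detection cells:", nbd, "\n")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## tabular I/O

#' Read a per-sample concentration table
#'
#' Expects delimited text with a header naming `sample_id`, `land_use` and
#' one column per element (mg/kg dry weight). Censored values may be coded
#' as `"<MDL"` sentinels, e.g. `"<0.004"`: the cell is flagged below
#' detection, the MDL is taken from the sentinel (or an `mdl_<element>`
#' column when present) and the working concentration is set by the
#' substitution policy -- half the MDL by default, the conventional choice
#' for summary statistics of censored environmental data.
#'
#' @param path file path to a delimited text file
#' @param sep field separator (default comma)
#' @param substitute below-detection substitution policy: `"half_mdl"`
#'   (default), `"mdl"`, or `"zero"`
#' @return a validated [SoilSamples-class] object; row order is preserved
#' @export
#' @seealso [writeSampleTable()]
readSampleTable <- function(path, sep = ",",
                            substitute = c("half_mdl", "mdl", "zero")) {
  substitute <- match.arg(substitute)
  tab <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  for (col in c("sample_id", "land_use"))
    if (!col %in% colnames(tab))
      stop(sprintf("missing required column '%s' in '%s'", col, path))
  mdl_cols <- grep("^mdl_", colnames(tab), value = TRUE)
  el_cols <- setdiff(colnames(tab), c("sample_id", "land_use", mdl_cols))
  if (!length(el_cols))
    stop("no element columns found")
  lu <- toupper(tab$land_use)
  bad <- which(!lu %in% .landUseCodes)
  if (length(bad))
    stop(sprintf("unknown land-use code '%s' in row %d",
                 tab$land_use[bad[1]], bad[1]))
  n <- nrow(tab)
  conc <- matrix(NA_real_, length(el_cols), n,
                 dimnames = list(el_cols, tab$sample_id))
  bd <- matrix(FALSE, length(el_cols), n, dimnames = dimnames(conc))
  mdl <- stats::setNames(rep(NA_real_, length(el_cols)), el_cols)
  for (el in el_cols) {
    raw <- trimws(tab[[el]])
    cens <- startsWith(raw, "<")
    vals <- suppressWarnings(as.numeric(ifelse(cens, sub("^<", "", raw), raw)))
    if (anyNA(vals))
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   raw[which(is.na(vals))[1]], el, which(is.na(vals))[1]))
    neg <- which(!cens & vals < 0)
    if (length(neg))
      stop(sprintf("negative concentration for '%s' in row %d (sample '%s')",
                   el, neg[1], tab$sample_id[neg[1]]))
    if (any(cens)) {
      mcol <- paste0("mdl_", el)
      lim <- if (mcol %in% colnames(tab))
        suppressWarnings(as.numeric(tab[[mcol]])) else vals
      if (any(cens & (is.na(lim) | lim <= 0)))
        stop(sprintf("below-detection cell without positive MDL for '%s'", el))
      mdl[el] <- max(lim[cens], na.rm = TRUE)
      vals[cens] <- switch(substitute,
                           half_mdl = lim[cens] / 2,
                           mdl = lim[cens],
                           zero = 0)
      bd[el, cens] <- TRUE
    }
    conc[el, ] <- vals
  }
  SoilSamples(conc, land_use = lu,
              below_detection = if (any(bd)) bd else NULL,
              mdl = if (any(!is.na(mdl))) mdl else NULL)
}

#' Write a per-sample concentration table
#'
#' Inverse of [readSampleTable()]: samples in rows, one column per element.
#' Below-detection cells are re-encoded as `"<MDL"` sentinels so that
#' read-write round-trips preserve the censoring information.
#'
#' @param x a [SoilSamples-class] object
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeSampleTable <- function(x, path) {
  conc <- concMatrix(x)
  bd <- belowDetection(x)
  mdl <- detectionLimits(x)
  cols <- lapply(rownames(conc), function(el) {
    v <- format(conc[el, ], trim = TRUE, scientific = FALSE, digits = 15)
    if (any(bd[el, ])) v[bd[el, ]] <- paste0("<", mdl[el])
    v
  })
  out <- data.frame(sample_id = colnames(conc), land_use = landUse(x),
                    stats::setNames(cols, rownames(conc)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## summaries

#' @rdname summarizeBySite
#' @export
setMethod("summarizeBySite", "SoilSamples", function(x) {
  conc <- concMatrix(x)
  lu <- landUse(x)
  sites <- intersect(.landUseCodes, unique(lu))
  out <- do.call(rbind, lapply(sites, function(site) {
    sub <- conc[, lu == site, drop = FALSE]
    data.frame(land_use = site, n = ncol(sub), element = rownames(sub),
               mean = rowMeans(sub),
               sd = if (ncol(sub) > 1) apply(sub, 1, stats::sd) else NA_real_,
               min = apply(sub, 1, min), max = apply(sub, 1, max),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
})

#' Fraction of samples exceeding a screening standard
#'
#' @param x a [SoilSamples-class] object
#' @param refs a [ReferenceSet-class] with the standard defined
#' @param standard standard name, e.g. `"TRV"` or `"DSQS"`
#' @param element element name
#' @return fraction in `[0, 1]` of samples with concentration strictly above
#'   the standard value
#' @export
#' @examples
#' refs <- defaultReferences()
#' conc <- matrix(c(2, 7, 8, 9), 1, dimnames = list("As", paste0("s", 1:4)))
#' x <- SoilSamples(conc, rep("IA", 4))
#' exceedanceFraction(x, refs, "TRV", "As")  # 3 of 4 above 6.0
exceedanceFraction <- function(x, refs, standard, element) {
  std <- standards(refs)
  if (!standard %in% rownames(std))
    stop(sprintf("unknown standard '%s'", standard))
  if (!element %in% colnames(std) || is.na(std[standard, element]))
    stop(sprintf("standard '%s' defines no value for element '%s'",
                 standard, element))
  if (!element %in% rownames(x))
    stop(sprintf("element '%s' not present in the sample table", element))
  mean(concMatrix(x)[element, ] > std[standard, element])
}
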