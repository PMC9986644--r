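#' @include AllGenerics.R
NULL

#' Construct an exposure profile
#'
#' With no overrides this returns the shipped USEPA point-estimate defaults
#' for the requested receptor (child: 15 kg, 200 mg/day soil ingestion,
#' 10 m3/day, 2100 cm2 skin, 0.2 mg/cm2 adherence, 6 y duration; adult:
#' 70 kg, 100 mg/day, 20 m3/day, 5800 cm2, 0.07 mg/cm2, 30 y). Both share
#' 350 days/year frequency, 0.1 dermal absorption, 0.61 dermal exposure
#' ratio, 1.3e9 m3/kg particulate emission factor and the 1e-6 kg/mg unit
#' conversion. Any parameter may be overridden by name.
#'
#' @param receptor `"child"` or `"adult"`
#' @param ... named overrides of the slots of
#'   [ExposureProfile-class] (e.g. `body_weight = 20`)
#' @return an [ExposureProfile-class] object
#' @export
#' @examples
#' exposureProfile("child")
exposureProfile <- function(receptor = c("child", "adult"), ...) {
  receptor <- match.arg(receptor)
  path <- system.file("extdata", "exposure_profiles.csv", package = "soilPTE",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  vals <- stats::setNames(as.numeric(tab[[receptor]]), tab$parameter)
  override <- list(...)
  bad <- setdiff(names(override), tab$parameter)
  if (length(bad))
    stop(sprintf("unknown exposure parameter '%s'", bad[1]))
  vals[names(override)] <- as.numeric(unlist(override))
  methods::new("ExposureProfile", receptor = receptor,
    body_weight = vals[["body_weight"]],
    exposure_frequency = vals[["exposure_frequency"]],
    exposure_duration = vals[["exposure_duration"]],
    ingestion_rate = vals[["ingestion_rate"]],
    inhalation_rate = vals[["inhalation_rate"]],
    skin_area = vals[["skin_area"]],
    adherence_factor = vals[["adherence_factor"]],
    dermal_absorption = vals[["dermal_absorption"]],
    dermal_exposure_ratio = vals[["dermal_exposure_ratio"]],
    particulate_emission_factor = vals[["particulate_emission_factor"]],
    conversion_factor = vals[["conversion_factor"]])
}

#' Averaging time in days
#'
#' 365 x 70 days for the carcinogenic endpoint; 365 x ED days for the
#' non-carcinogenic endpoint.
#'
#' @param profile an [ExposureProfile-class]
#' @param carcinogenic logical
#' @return averaging time, days
#' @export
averagingTime <- function(profile, carcinogenic = FALSE) {
  if (carcinogenic) 365 * 70 else 365 * profile@exposure_duration
}

setMethod("show", "ExposureProfile", function(object) {
  cat(sprintf(
    "ExposureProfile '%s': BW %g kg, EF %g d/y, ED %g y, IRS %g mg/d,\n",
    object@receptor, object@body_weight, object@exposure_frequency,
    object@exposure_duration, object@ingestion_rate))
  cat(sprintf("  InhR %g m3/d, SA %g cm2, AF %g mg/cm2, ABS %g, PEF %g m3/kg\n",
              object@inhalation_rate, object@skin_area,
              object@adherence_factor, object@dermal_absorption,
              object@particulate_emission_factor))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## chronic daily intakes

#' Chronic daily intake via incidental soil ingestion
#'
#' CDI = CS x IRS x EF x ED / (BW x AT) x CFu, mg/kg/day. The averaging
#' time is selected by the endpoint: for non-carcinogens AT = 365 x ED, so
#' the non-carcinogenic CDI is algebraically independent of the exposure
#' duration.
#'
#' @param cs soil concentration, mg/kg (>= 0); vectorised
#' @param profile an [ExposureProfile-class]
#' @param carcinogenic use the 70-year carcinogenic averaging time?
#' @return dose rate, mg/kg/day
#' @export
#' @examples
#' cdiIngestion(1, exposureProfile("child"))   # 1.2785e-5
cdiIngestion <- function(cs, profile, carcinogenic = FALSE) {
  if (any(cs < 0)) stop("concentrations must be non-negative")
  at <- averagingTime(profile, carcinogenic)
  cs * profile@ingestion_rate * profile@exposure_frequency *
    profile@exposure_duration / (profile@body_weight * at) *
    profile@conversion_factor
}

#' Chronic daily intake via dermal contact
#'
#' CDI = CS x SA x AF x ABS x EF x ED / (BW x AT) x CFu, mg/kg/day. The
#' dermal exposure ratio FE is carried in the profile but not part of the
#' dose equation by default (`include_fe = TRUE` multiplies it in).
#'
#' @inheritParams cdiIngestion
#' @param include_fe multiply the dermal exposure ratio into the dose?
#' @return dose rate, mg/kg/day
#' @export
cdiDermal <- function(cs, profile, carcinogenic = FALSE, include_fe = FALSE) {
  if (any(cs < 0)) stop("concentrations must be non-negative")
  at <- averagingTime(profile, carcinogenic)
  fe <- if (include_fe) profile@dermal_exposure_ratio else 1
  cs * profile@skin_area * profile@adherence_factor *
    profile@dermal_absorption * fe * profile@exposure_frequency *
    profile@exposure_duration / (profile@body_weight * at) *
    profile@conversion_factor
}

#' Chronic daily intake via particulate inhalation
#'
#' CDI = CS x InhR x EF x ED / (PEF x BW x AT), mg/kg/day. The particulate
#' emission factor converts the soil concentration to an air concentration,
#' so no mg-to-kg conversion factor appears.
#'
#' @inheritParams cdiIngestion
#' @return dose rate, mg/kg/day
#' @export
cdiInhalation <- function(cs, profile, carcinogenic = FALSE) {
  if (any(cs < 0)) stop("concentrations must be non-negative")
  at <- averagingTime(profile, carcinogenic)
  cs * profile@inhalation_rate * profile@exposure_frequency *
    profile@exposure_duration /
    (profile@particulate_emission_factor * profile@body_weight * at)
}

## ---------------------------------------------------------------------------
## toxicity table

#' Construct a toxicity table
#'
#' @param rfd numeric matrix of reference doses, elements x routes
#'   (`ingestion`, `dermal`, `inhalation`); `NA` = not assessed
#' @param csf numeric matrix of cancer slope factors, same shape
#' @return a [ToxicityTable-class] object
#' @export
toxicityTable <- function(rfd, csf) {
  methods::new("ToxicityTable", rfd = as.matrix(rfd), csf = as.matrix(csf))
}

#' Shipped default toxicity values
#'
#' Reference doses and cancer slope factors drawn from standard USEPA
#' compilations (IRIS/RSL-style values commonly used in soil risk
#' screening); these are package defaults, fully overridable via
#' [toxicityTable()] or by editing a copy of the shipped CSV. Dermal values
#' are oral values adjusted by gastrointestinal absorption where a
#' compilation provides one.
#'
#' @return a [ToxicityTable-class] object
#' @export
#' @examples
#' rfd(defaultToxicity())
defaultToxicity <- function() {
  path <- system.file("extdata", "toxicity.csv", package = "soilPTE",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  els <- unique(tab$element)
  mk <- function(col) {
    m <- matrix(NA_real_, length(els), length(.riskRoutes),
                dimnames = list(els, .riskRoutes))
    for (i in seq_len(nrow(tab)))
      m[tab$element[i], tab$route[i]] <- tab[[col]][i]
    m
  }
  toxicityTable(mk("rfd"), mk("csf"))
}

#' @rdname ToxicityTable-class
#' @param x a `ToxicityTable`
#' @export
rfd <- function(x) x@rfd

#' @rdname ToxicityTable-class
#' @export
csf <- function(x) x@csf

setMethod("show", "ToxicityTable", function(object) {
  cat("ToxicityTable:", nrow(object@rfd), "elements;",
      sum(!is.na(object@rfd)), "RfD and", sum(!is.na(object@csf)),
      "CSF entries defined\n")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## quotients and risks

#' Hazard quotient
#'
#' HQ = CDI / RfD; HQ > 1 flags potential non-carcinogenic concern. An
#' undefined RfD yields `NA` -- the pair is "not assessed", never zero.
#'
#' @param cdi chronic daily intake, mg/kg/day
#' @param rfd reference dose, mg/kg/day (> 0) or `NA`
#' @return dimensionless hazard quotient (or `NA`)
#' @export
hazardQuotient <- function(cdi, rfd) {
  if (any(rfd <= 0, na.rm = TRUE)) stop("reference doses must be positive")
  cdi / rfd
}

#' Hazard index
#'
#' Sum of hazard quotients across routes (and, optionally, across
#' elements). Undefined ("not assessed") quotients are excluded with a
#' note; an all-undefined input is an error.
#'
#' @param hq numeric vector or matrix (elements x routes) of hazard
#'   quotients, `NA` = not assessed
#' @param across_elements when `hq` is a matrix, also sum over elements to
#'   a single site-level HI?
#' @param quiet suppress the note about excluded pairs?
#' @return HI (scalar, or per-element vector for matrix input with
#'   `across_elements = FALSE`)
#' @export
hazardIndex <- function(hq, across_elements = FALSE, quiet = FALSE) {
  if (all(is.na(hq))) stop("no defined hazard quotient to sum")
  if (anyNA(hq) && !quiet)
    message(sum(is.na(hq)), " element-route pair(s) not assessed; ",
            "excluded from HI")
  if (is.matrix(hq) && !across_elements) rowSums(hq, na.rm = TRUE)
  else sum(hq, na.rm = TRUE)
}

#' Carcinogenic risk for one route
#'
#' CR = CDI x CSF, the incremental lifetime cancer probability attributable
#' to one element via one route. An undefined slope factor yields `NA`.
#'
#' @param cdi carcinogenic-endpoint chronic daily intake, mg/kg/day
#' @param csf cancer slope factor, (mg/kg/day)^-1 (> 0) or `NA`
#' @return dimensionless risk (or `NA`)
#' @export
cancerRisk <- function(cdi, csf) {
  if (any(csf <= 0, na.rm = TRUE)) stop("slope factors must be positive")
  cdi * csf
}

#' Lifetime cancer risk across routes
#'
#' @param cr numeric vector of per-route cancer risks; `NA` entries
#'   (routes without a slope factor) are excluded
#' @return summed lifetime cancer risk; `NA` if no route is assessed
#' @export
lifetimeCancerRisk <- function(cr) {
  if (all(is.na(cr))) return(NA_real_)
  sum(cr, na.rm = TRUE)
}

#' Compare a cancer risk with the USEPA acceptable window
#'
#' The conventional acceptable incremental risk window is 1e-6 to 1e-4.
#'
#' @param cr cancer risk value(s)
#' @return character: `"below"`, `"within"` or `"exceeds"`
#' @export
cancerRiskFlag <- function(cr) {
  ifelse(is.na(cr), NA_character_,
         ifelse(cr > 1e-4, "exceeds", ifelse(cr < 1e-6, "below", "within")))
}

## ---------------------------------------------------------------------------
## site-level report

#' Multi-route health risk report for land-use sites
#'
#' Runs the full USEPA chain on site-mean concentrations for one or more
#' receptors: per (receptor, site, element, route) the non-carcinogenic and
#' carcinogenic chronic daily intakes, hazard quotient and cancer risk;
#' per (receptor, site, element) the hazard index and lifetime cancer
#' risk; and per (receptor, site) the element-summed totals. Dermal and
#' inhalation RfDs missing from the toxicity table fall back to the oral
#' value and are flagged in the detail table.
#'
#' @param x a [SoilSamples-class] object or a site-summary `data.frame`
#'   from [summarizeBySite()]
#' @param profiles list of [ExposureProfile-class] objects (default the
#'   shipped child and adult)
#' @param tox a [ToxicityTable-class] (default [defaultToxicity()])
#' @param include_fe passed to [cdiDermal()]
#' @return list with `detail` (long data.frame: receptor, land_use,
#'   element, route, cdi_nc, cdi_car, hq, cr, rfd_fallback, cr_flag),
#'   `by_element` (receptor, land_use, element, hi, ltcr) and `summary`
#'   (receptor, land_use, hi_total, ltcr_total)
#' @export
healthRiskReport <- function(x,
                             profiles = list(exposureProfile("child"),
                                             exposureProfile("adult")),
                             tox = defaultToxicity(),
                             include_fe = FALSE) {
  summary <- if (methods::is(x, "SoilSamples")) summarizeBySite(x) else x
  elements <- intersect(.pteElements, unique(summary$element))
  means <- .siteMeansWide(summary, elements)
  rfdm <- rfd(tox); csfm <- csf(tox)
  detail <- list()
  for (profile in profiles) {
    rec <- profile@receptor
    for (site in rownames(means)) {
      for (el in elements) {
        cs <- means[site, el]
        cdi_nc <- c(ingestion = cdiIngestion(cs, profile, FALSE),
                    dermal = cdiDermal(cs, profile, FALSE, include_fe),
                    inhalation = cdiInhalation(cs, profile, FALSE))
        cdi_car <- c(ingestion = cdiIngestion(cs, profile, TRUE),
                     dermal = cdiDermal(cs, profile, TRUE, include_fe),
                     inhalation = cdiInhalation(cs, profile, TRUE))
        rfd_el <- if (el %in% rownames(rfdm)) rfdm[el, ] else
          stats::setNames(rep(NA_real_, 3), .riskRoutes)
        fallback <- is.na(rfd_el) & !is.na(rfd_el["ingestion"])
        fallback["ingestion"] <- FALSE
        rfd_eff <- ifelse(is.na(rfd_el), rfd_el["ingestion"], rfd_el)
        csf_el <- if (el %in% rownames(csfm)) csfm[el, ] else
          stats::setNames(rep(NA_real_, 3), .riskRoutes)
        hq <- hazardQuotient(cdi_nc, rfd_eff)
        cr <- cancerRisk(cdi_car, csf_el)
        detail[[length(detail) + 1L]] <- data.frame(
          receptor = rec, land_use = site, element = el,
          route = .riskRoutes, cdi_nc = unname(cdi_nc),
          cdi_car = unname(cdi_car), hq = unname(hq), cr = unname(cr),
          rfd_fallback = unname(fallback),
          cr_flag = cancerRiskFlag(unname(cr)),
          stringsAsFactors = FALSE)
      }
    }
  }
  detail <- do.call(rbind, detail)
  agg <- function(v) if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  by_element <- do.call(rbind, lapply(
    split(detail, detail[c("element", "land_use", "receptor")], drop = TRUE),
    function(d) data.frame(receptor = d$receptor[1], land_use = d$land_use[1],
                           element = d$element[1], hi = agg(d$hq),
                           ltcr = agg(d$cr), stringsAsFactors = FALSE)))
  rownames(by_element) <- NULL
  summary_tab <- do.call(rbind, lapply(
    split(by_element, by_element[c("land_use", "receptor")], drop = TRUE),
    function(d) data.frame(receptor = d$receptor[1], land_use = d$land_use[1],
                           hi_total = agg(d$hi), ltcr_total = agg(d$ltcr),
                           stringsAsFactors = FALSE)))
  rownames(summary_tab) <- NULL
  list(detail = detail, by_element = by_element, summary = summary_tab)
}
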