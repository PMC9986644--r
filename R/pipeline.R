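#' @include AllGenerics.R
NULL

#' Shipped reference index values
#'
#' The packaged fixture of study-area index results used as a regression
#' surface: contamination factors, degrees of contamination (with category
#' labels), geoaccumulation indices, ecological risk factors and PERI (with
#' risk levels), one row per reported cell.
#'
#' @return `data.frame` with columns `table` (`cf`, `cd`, `igeo`, `er`,
#'   `peri`), `land_use`, `element` (empty for the site-level aggregates),
#'   `value`, `label`
#' @export
referenceIndexValues <- function() {
  path <- system.file("extdata", "reference_indices.csv", package = "soilPTE",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(element = "character", label = "character"))
}

#' Recompute the reference index tables and compare
#'
#' Recomputes every contamination factor, degree of contamination,
#' geoaccumulation index, ecological risk factor and PERI cell from the
#' shipped site-mean concentrations and backgrounds, and compares them with
#' the shipped reference values, reporting per-cell and per-table maximum
#' absolute and relative deviations. This is the executable record of the
#' index-reproduction checks.
#'
#' @param refs a [ReferenceSet-class] (default [defaultReferences()])
#' @param site_summary site-mean table (default [defaultSiteSpecs()])
#' @param reference reference cell values (default [referenceIndexValues()])
#' @return list with `cells` (per-cell comparison: table, land_use,
#'   element, computed, reference, abs_dev, rel_dev) and `summary`
#'   (per-table max_abs_dev, max_rel_dev, n_cells)
#' @export
#' @examples
#' rep <- verifyReferenceIndices()
#' rep$summary
verifyReferenceIndices <- function(refs = defaultReferences(),
                                   site_summary = defaultSiteSpecs(),
                                   reference = referenceIndexValues()) {
  ind <- siteIndices(site_summary, refs)
  eco <- siteEcoRisk(site_summary, refs)
  lookup <- function(tab, lu, el) {
    row_i <- switch(tab, cf = , igeo = , cd = ind, er = , peri = eco)
    r <- row_i[row_i$land_use == lu, , drop = FALSE]
    col <- switch(tab, cf = paste0("cf_", el), igeo = paste0("igeo_", el),
                  cd = "c_d", er = paste0("er_", el), peri = "peri")
    r[[col]]
  }
  computed <- mapply(lookup, reference$table, reference$land_use,
                     reference$element)
  cells <- data.frame(table = reference$table, land_use = reference$land_use,
                      element = reference$element, computed = computed,
                      reference = reference$value,
                      abs_dev = abs(computed - reference$value),
                      rel_dev = abs(computed - reference$value) /
                        abs(reference$value),
                      stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(split(cells, cells$table), function(d)
    data.frame(table = d$table[1], n_cells = nrow(d),
               max_abs_dev = max(d$abs_dev), max_rel_dev = max(d$rel_dev),
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(cells = cells, summary = summary)
}

#' Run the full appraisal pipeline
#'
#' Orchestrates an end-to-end run: obtain samples (generate them from the
#' site spec when none are given), summarise by site, compute pollution
#' indices, ecological risk, multi-route health risk for child and adult
#' receptors, fit the PMF receptor model, and write every result plus a
#' JSON manifest to the output directory. Deterministic for a fixed seed:
#' two runs with the same configuration produce identical files. On any
#' stage failure the partial outputs are removed.
#'
#' @param out_dir output directory (created if needed)
#' @param samples optional [SoilSamples-class]; when `NULL`, generated from
#'   `spec` with `seed`
#' @param spec site spec for generation (default [defaultSiteSpecs()])
#' @param refs a [ReferenceSet-class]
#' @param seed integer seed (recorded in the manifest and output headers)
#' @param n_factors,n_runs PMF settings
#' @param cdScheme,periScheme classification scheme names
#' @param tox a [ToxicityTable-class]
#' @return (invisibly) list with the computed objects and `manifest`
#' @export
runPipeline <- function(out_dir, samples = NULL, spec = defaultSiteSpecs(),
                        refs = defaultReferences(), seed = 1,
                        n_factors = 3, n_runs = 20,
                        cdScheme = "cd_inferred",
                        periScheme = "peri_inferred",
                        tox = defaultToxicity()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(sprintf("# soilPTE pipeline output; seed=%d", seed), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    written <<- c(written, path)
    path
  }
  tryCatch({
    bg <- background(refs)
    missing_el <- setdiff(intersect(.pteElements, unique(spec$element)),
                          names(bg))
    if (length(missing_el))
      stop(sprintf("reference set lacks element '%s'", missing_el[1]))
    if (is.null(samples))
      samples <- generateSiteSamples(spec, seed = seed)
    site_summary <- summarizeBySite(samples)
    emit(site_summary, "site_summary.csv")
    ind <- siteIndices(site_summary, refs, cdScheme = cdScheme)
    emit(ind, "indices.csv")
    eco <- siteEcoRisk(site_summary, refs, periScheme = periScheme)
    emit(eco, "eco_risk.csv")
    hr <- healthRiskReport(site_summary, tox = tox)
    emit(hr$detail, "health_risk_detail.csv")
    emit(hr$by_element, "health_risk_by_element.csv")
    emit(hr$summary, "health_risk_summary.csv")
    mdl <- detectionLimits(refs)
    pmf <- fitPMF(samples, mdl = mdl[rownames(samples)],
                  n_factors = n_factors, n_runs = n_runs, seed = seed)
    emit(as.data.frame(profiles(pmf)), "pmf_profiles.csv")
    emit(as.data.frame(contributions(pmf)), "pmf_contributions.csv")
    emit(runTable(pmf), "pmf_runs.csv")
    emit(as.data.frame(factorContributions(pmf)), "pmf_percentages.csv")
    manifest <- list(
      package = "soilPTE",
      version = as.character(utils::packageVersion("soilPTE")),
      seed = seed,
      n_samples = ncol(samples),
      elements = rownames(samples),
      land_uses = as.list(table(landUse(samples))),
      pmf = list(n_factors = n_factors, n_runs = n_runs,
                 q_true = qTrue(pmf), q_robust = qRobust(pmf),
                 best_run_seed = pmf@run_seed),
      schemes = list(cd = cdScheme, peri = periScheme),
      outputs = basename(written))
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, manifest_path)
    invisible(list(samples = samples, site_summary = site_summary,
                   indices = ind, eco_risk = eco, health_risk = hr,
                   pmf = pmf, manifest = manifest))
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
  })
}
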