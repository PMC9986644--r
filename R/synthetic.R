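#' @include AllGenerics.R
NULL

#' Default per-site generation targets
#'
#' The shipped site specification: for each of the eleven land-use classes,
#' the sample count and the per-element target mean, standard deviation and
#' concentration range observed in the study area (71 samples in total:
#' PA 3, PG 8, M 8, BF 8, IA 4, PP 8, MW 8, BS 3, PS 8, RA 8, WDA 5).
#'
#' @return `data.frame` with columns `land_use`, `n`, `element`, `mean`,
#'   `sd`, `min`, `max` (mg/kg)
#' @export
#' @examples
#' spec <- defaultSiteSpecs()
#' sum(spec$n[!duplicated(spec$land_use)])  # 71
defaultSiteSpecs <- function() {
  path <- system.file("extdata", "site_summary.csv", package = "soilPTE",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

## mean of a normal(mu, sd) truncated to [lo, hi]
.truncMean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

## variance of the same truncated normal (for the Newton step)
.truncVar <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  d <- (stats::dnorm(a) - stats::dnorm(b)) / z
  sd^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / z - d^2)
}

## location parameter whose truncated mean equals `target`; Newton in mu
## (d mean / d mu = truncated variance / sd^2)
.recenter <- function(target, sd, lo, hi, iters = 3) {
  mu <- target
  for (i in seq_len(iters)) {
    m <- .truncMean(mu, sd, lo, hi)
    v <- .truncVar(mu, sd, lo, hi)
    step <- (m - target) / max(v / sd^2, 1e-6)
    mu <- mu - step
  }
  mu
}

.rtruncnorm <- function(n, mu, sd, lo, hi) {
  if (sd <= 0) return(rep(mu, n))
  pl <- stats::pnorm(lo, mu, sd)
  pu <- stats::pnorm(hi, mu, sd)
  q <- stats::qnorm(pl + stats::runif(n) * (pu - pl), mu, sd)
  pmin(pmax(q, lo), hi)  # guard the inversion's floating endpoints
}

#' Generate synthetic per-site samples
#'
#' Draws each (site, element) from a normal distribution truncated to the
#' specified concentration range. Because truncation shifts the mean, the
#' location parameter is re-centred by a short Newton iteration (default 3
#' steps, `recenter = TRUE`) so the truncated-distribution mean equals the
#' target mean. Elements are drawn independently within a site. The output
#' is byte-identical for a fixed seed and spec.
#'
#' @param spec a site-spec `data.frame` as from [defaultSiteSpecs()]
#' @param seed integer seed
#' @param recenter re-centre the location parameter for the truncation?
#' @return a [SoilSamples-class] object with `sum(n)` samples
#' @export
#' @examples
#' x <- generateSiteSamples(defaultSiteSpecs(), seed = 1)
#' ncol(x)  # 71
generateSiteSamples <- function(spec, seed = 1, recenter = TRUE) {
  req <- c("land_use", "n", "element", "mean", "sd", "min", "max")
  if (!all(req %in% colnames(spec)))
    stop("spec must have columns ", paste(req, collapse = ", "))
  bad <- which(spec$mean < spec$min | spec$mean > spec$max | spec$sd < 0)
  if (length(bad))
    stop(sprintf("infeasible spec row %d (%s %s): mean outside range or sd < 0",
                 bad[1], spec$land_use[bad[1]], spec$element[bad[1]]))
  sites <- unique(spec$land_use)
  elements <- unique(spec$element)
  set.seed(as.integer(seed))
  blocks <- vector("list", length(sites))
  lus <- character(0)
  for (si in seq_along(sites)) {
    site <- sites[si]
    sub <- spec[spec$land_use == site, , drop = FALSE]
    n <- sub$n[1]
    m <- matrix(NA_real_, length(elements), n,
                dimnames = list(elements, paste0(site, "_", seq_len(n))))
    for (el in elements) {
      row <- sub[sub$element == el, , drop = FALSE]
      if (!nrow(row))
        stop(sprintf("spec lacks element '%s' for site '%s'", el, site))
      mu <- if (recenter && row$sd > 0)
        .recenter(row$mean, row$sd, row$min, row$max) else row$mean
      m[el, ] <- .rtruncnorm(n, mu, row$sd, row$min, row$max)
    }
    blocks[[si]] <- m
    lus <- c(lus, rep(site, n))
  }
  SoilSamples(do.call(cbind, blocks), land_use = lus)
}

#' Default source profiles for mixture simulation
#'
#' Three synthetic source signatures (mg/kg per unit contribution) echoing
#' the qualitative source structure of urban soils: a traffic/mixed
#' anthropogenic source dominated by Pb and Cu, a geogenic source dominated
#' by Cr, and an urban-industrial source carrying As, Ni and Cd. Each
#' source has a dominant tracer (Pb, Cr, Cd respectively) with only trace
#' cross-loadings: factor-analytic recovery is only well-posed when the
#' signatures are sufficiently distinct, so an identifiable truth is a
#' design requirement of the harness. They are a validation fixture, not a
#' claim about any real source.
#'
#' @return matrix, sources x elements
#' @export
defaultSourceProfiles <- function() {
  matrix(c(
    ## As    Cd    Pb    Cr    Ni    Cu
    0.5, 0.05, 30.0,  0.5,  2.0, 35.0,   # traffic / mixed anthropogenic
    2.0, 0.01,  0.5, 40.0,  6.0,  2.0,   # geogenic (crustal)
    8.0, 1.00,  1.0,  1.0, 15.0,  6.0),  # urban-industrial
    nrow = 3, byrow = TRUE,
    dimnames = list(c("traffic", "geogenic", "industrial"), .pteElements))
}

#' Generate a known-source synthetic mixture
#'
#' Builds X = G F x (1 + noise) with non-negative contributions G drawn
#' from a lognormal law (heavy-tailed source strengths, the realistic shape
#' for environmental source activity) and multiplicative Gaussian noise of
#' the stated fraction. Values are floored at a small positive multiple of
#' the MDL so the table passes validation. Returns the ground truth for
#' recovery tests.
#'
#' @param profiles sources x elements non-negative matrix
#'   (default [defaultSourceProfiles()])
#' @param n_samples number of samples
#' @param seed integer seed
#' @param noise_fraction relative noise level (0 gives X = G F exactly)
#' @param meanlog,sdlog parameters of the lognormal contribution law
#' @param mdl named per-element detection limits used for flooring
#' @param land_use placeholder land-use code(s) for the generated table
#' @return list with `samples` (a [SoilSamples-class]), `X` (samples x
#'   elements matrix), `G` (true contributions), `F` (true profiles) and
#'   `true_shares` (elements x sources percentage matrix)
#' @export
generateMixture <- function(profiles = defaultSourceProfiles(),
                            n_samples = 200, seed = 1, noise_fraction = 0.05,
                            meanlog = 0, sdlog = 1,
                            mdl = stats::setNames(
                              defaultReferences()@mdl[colnames(profiles)],
                              colnames(profiles)),
                            land_use = "IA") {
  profiles <- as.matrix(profiles)
  if (any(profiles < 0)) stop("source profiles must be non-negative")
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  a <- nrow(profiles)
  p <- ncol(profiles)
  set.seed(as.integer(seed))
  G <- matrix(stats::rlnorm(n_samples * a, meanlog, sdlog), n_samples, a,
              dimnames = list(paste0("S", seq_len(n_samples)),
                              rownames(profiles)))
  X0 <- G %*% profiles
  X <- X0
  if (noise_fraction > 0)
    X <- X0 * (1 + noise_fraction * matrix(stats::rnorm(n_samples * p),
                                           n_samples, p))
  floor_at <- if (!is.null(mdl) && !anyNA(mdl))
    matrix(mdl[colnames(profiles)] / 2, n_samples, p, byrow = TRUE)
  else 1e-6
  X <- pmax(X, floor_at)
  mass <- t(profiles) * rep(colSums(G), each = p)  # elements x sources
  samples <- SoilSamples(t(X), land_use = rep(land_use, length.out = n_samples),
                         mdl = mdl)
  list(samples = samples, X = X, G = G, F = profiles,
       true_shares = 100 * mass / rowSums(mass))
}
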