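#' @include AllGenerics.R
NULL

#' Build the PMF uncertainty matrix
#'
#' Cell-wise measurement uncertainties for the weighted factorization:
#' below or at the detection limit, alpha = 5/6 x MDL; above it,
#' alpha = error_fraction x X + MDL (error fraction 0.05 by default).
#' Equality with the MDL takes the below-detection rule.
#'
#' @param x a [SoilSamples-class] object or a samples x elements numeric
#'   matrix
#' @param mdl named numeric of per-element detection limits (mg/kg, > 0);
#'   defaults to the MDLs carried by `x` when it is a `SoilSamples`
#' @param error_fraction relative measurement error for quantified cells
#' @return list with `alpha` (samples x elements matrix, all > 0) and
#'   `rule` (character matrix, `"below_mdl"` / `"above_mdl"`)
#' @export
#' @examples
#' buildUncertainty(matrix(c(0.6, 2), 2, 1, dimnames = list(NULL, "Cd")),
#'                  mdl = c(Cd = 1.2))
buildUncertainty <- function(x, mdl = NULL, error_fraction = 0.05) {
  if (error_fraction <= 0) stop("error_fraction must be positive")
  if (methods::is(x, "SoilSamples")) {
    if (is.null(mdl)) {
      mdl <- detectionLimits(x)
      mdl <- mdl[!is.na(mdl)]
    }
    X <- t(concMatrix(x))
  } else X <- as.matrix(x)
  els <- colnames(X)
  missing_mdl <- setdiff(els, names(mdl))
  if (length(missing_mdl))
    stop(sprintf("missing MDL for element '%s'", missing_mdl[1]))
  if (any(mdl[els] <= 0)) stop("MDLs must be strictly positive")
  mdlrow <- matrix(mdl[els], nrow(X), ncol(X), byrow = TRUE)
  below <- X <= mdlrow
  alpha <- ifelse(below, 5 / 6 * mdlrow, error_fraction * X + mdlrow)
  rule <- ifelse(below, "below_mdl", "above_mdl")
  dimnames(alpha) <- dimnames(rule) <- dimnames(X)
  list(alpha = alpha, rule = rule)
}

## Weighted hierarchical alternating least squares. Each factor's
## contribution column and profile row is the exact minimiser of the
## weighted objective with everything else held fixed, so Q is
## non-increasing by construction.
.pmfHALS <- function(X, W, G, F, max_iter, tol) {
  q_trace <- numeric(max_iter)
  E <- X - G %*% F
  q_prev <- sum(W * E * E)
  q_scale <- sum(W * X * X)  # negligible-Q floor for noise-free data
  a <- ncol(G)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    for (k in seq_len(a)) {
      Rk <- E + outer(G[, k], F[k, ])
      num <- (W * Rk) %*% F[k, ]
      den <- W %*% (F[k, ]^2)
      gk <- ifelse(den > 0, pmax(0, num / den), 0)
      num2 <- crossprod(W * Rk, gk)
      den2 <- crossprod(W, gk^2)
      fk <- ifelse(den2 > 0, pmax(0, num2 / den2), 0)
      G[, k] <- gk
      F[k, ] <- fk
      E <- Rk - outer(as.numeric(gk), as.numeric(fk))
    }
    q <- sum(W * E * E)
    q_trace[it] <- q
    if (is.nan(q)) stop("PMF objective became NaN")
    if (q <= .Machine$double.eps * q_scale ||
        abs(q_prev - q) <= tol * max(q_prev, .Machine$double.xmin)) {
      converged <- TRUE
      break
    }
    q_prev <- q
  }
  list(G = G, F = F, q = q_trace[it], q_trace = q_trace[seq_len(it)],
       converged = converged)
}

#' Fit the positive matrix factorization receptor model
#'
#' Decomposes the concentration matrix as X = G F + E with non-negative
#' factor contributions G (samples x factors) and profiles F (factors x
#' elements), minimising the uncertainty-weighted objective
#' Q = sum((E / alpha)^2) by hierarchical alternating least squares from
#' seeded random starts. Each run's Q sequence is monotone non-increasing;
#' the run with the lowest robust Q wins. Profiles are normalised to unit
#' row sum with the scale absorbed into the contributions (the usual
#' resolution of the factorization's scale indeterminacy).
#'
#' @param x a [SoilSamples-class] object or a samples x elements matrix
#' @param alpha uncertainty matrix from [buildUncertainty()] (the list or
#'   its `alpha` component); defaults to `buildUncertainty(x, mdl)`
#' @param n_factors number of factors `a`, with `2 <= a < min(dim(X))`
#' @param n_runs random restarts (default 20)
#' @param seed integer seed; run `r` uses `seed + r - 1`
#' @param max_iter iteration cap per run
#' @param tol relative Q-change convergence tolerance
#' @param mdl passed to [buildUncertainty()] when `alpha` is missing
#' @param outlier_threshold scaled-residual cap for the robust Q
#' @param init optional deterministic start: a list with non-negative
#'   matrices `G` (samples x factors) and `F` (factors x elements); when
#'   given, a single run is performed from it (no random restarts)
#' @return a [PMFSolution-class]; `runTable()` lists every run's seed,
#'   Q(true), Q(robust) and convergence flag
#' @export
fitPMF <- function(x, alpha = NULL, n_factors = 3, n_runs = 20,
                   seed = 1, max_iter = 2000, tol = 1e-10, mdl = NULL,
                   outlier_threshold = 4, init = NULL) {
  X <- if (methods::is(x, "SoilSamples")) t(concMatrix(x)) else as.matrix(x)
  if (anyNA(X) || any(!is.finite(X)))
    stop("concentration matrix contains NA or non-finite values")
  if (is.null(alpha)) alpha <- buildUncertainty(x, mdl = mdl)
  if (is.list(alpha)) alpha <- alpha$alpha
  alpha <- as.matrix(alpha)
  if (!identical(dim(alpha), dim(X)))
    stop("uncertainty matrix must match the concentration matrix")
  if (any(alpha <= 0)) stop("uncertainties must be strictly positive")
  n_factors <- as.integer(n_factors)
  if (n_factors < 2 || n_factors >= min(dim(X)))
    stop("n_factors must satisfy 2 <= a < min(n_samples, n_elements)")
  if (n_runs < 1) stop("n_runs must be at least 1")
  if (!is.null(init)) {
    if (!identical(dim(init$G), c(nrow(X), as.integer(n_factors))) ||
        !identical(dim(init$F), c(as.integer(n_factors), ncol(X))))
      stop("'init' matrices do not match the problem dimensions")
    if (any(init$G < 0) || any(init$F < 0))
      stop("'init' matrices must be non-negative")
    n_runs <- 1L
  }
  W <- 1 / alpha^2
  col_scale <- pmax(colMeans(X), .Machine$double.eps)
  best <- NULL
  runs <- data.frame(run = integer(0), seed = integer(0),
                     q_true = numeric(0), q_robust = numeric(0),
                     converged = logical(0))
  for (r in seq_len(n_runs)) {
    run_seed <- as.integer(seed + r - 1)
    set.seed(run_seed)
    if (is.null(init)) {
      G0 <- matrix(stats::runif(nrow(X) * n_factors, 0.1, 2), nrow(X))
      F0 <- matrix(stats::runif(n_factors * ncol(X), 0.1, 2), n_factors) *
        matrix(col_scale / n_factors, n_factors, ncol(X), byrow = TRUE)
    } else {
      G0 <- init$G
      F0 <- init$F
    }
    fit <- .pmfHALS(X, W, G0, F0, max_iter, tol)
    sr <- (X - fit$G %*% fit$F) / alpha
    q_true <- sum(sr^2)
    q_rob <- sum(pmin(sr^2, outlier_threshold^2))
    runs <- rbind(runs, data.frame(run = r, seed = run_seed, q_true = q_true,
                                   q_robust = q_rob, converged = fit$converged))
    if (is.null(best) || q_rob < best$q_rob)
      best <- list(fit = fit, q_true = q_true, q_rob = q_rob, seed = run_seed)
  }
  if (!any(runs$converged))
    stop(paste0("no PMF run converged within ", max_iter,
                " iterations; final Q values: ",
                paste(signif(runs$q_true, 6), collapse = ", ")))
  G <- best$fit$G
  F <- best$fit$F
  ## unit-sum profile normalisation; scale moves into contributions
  s <- rowSums(F)
  keep <- s > 0
  F[keep, ] <- F[keep, , drop = FALSE] / s[keep]
  G[, keep] <- sweep(G[, keep, drop = FALSE], 2, s[keep], `*`)
  recon <- G %*% F
  E <- X - recon
  r2 <- vapply(seq_len(ncol(X)), function(j) {
    if (stats::sd(X[, j]) == 0 || stats::sd(recon[, j]) == 0) return(NA_real_)
    stats::cor(X[, j], recon[, j])^2
  }, numeric(1))
  names(r2) <- colnames(X)
  dimnames(G) <- list(rownames(X), paste0("F", seq_len(n_factors)))
  dimnames(F) <- list(paste0("F", seq_len(n_factors)), colnames(X))
  methods::new("PMFSolution", n_factors = n_factors, profiles = F,
               contributions = G, residuals = E, alpha = alpha,
               q_true = best$q_true,
               q_robust = best$q_rob, q_trace = best$fit$q_trace,
               run_seed = best$seed, converged = best$fit$converged,
               r2 = r2, runs = runs)
}

#' Robust Q for a fitted solution
#'
#' Recomputes the robust objective: cells whose absolute scaled residual
#' exceeds the threshold are down-weighted so each contributes at most
#' threshold^2 (the conventional robust-mode capping rule). With no
#' outlying cell, Q(robust) = Q(true); capping never increases Q.
#'
#' @param solution a [PMFSolution-class]
#' @param outlier_threshold positive scaled-residual cutoff (default 4)
#' @return robust Q value
#' @export
robustQ <- function(solution, outlier_threshold = 4) {
  if (outlier_threshold <= 0) stop("outlier threshold must be positive")
  sr <- scaledResiduals(solution)
  sum(pmin(sr^2, outlier_threshold^2))
}

#' Per-element factor contribution percentages
#'
#' For each element, the share of the total reconstructed mass across all
#' samples attributable to each factor, in percent; each element row sums
#' to 100. An element with zero reconstructed mass has an undefined share
#' (`NaN`) and is flagged with a warning.
#'
#' @param solution a [PMFSolution-class]
#' @return matrix, elements x factors, rows summing to 100
#' @export
factorContributions <- function(solution) {
  G <- contributions(solution)
  F <- profiles(solution)
  mass <- t(F) * rep(colSums(G), each = ncol(F))  # elements x factors
  dimnames(mass) <- list(colnames(F), rownames(F))
  tot <- rowSums(mass)
  if (any(tot == 0))
    warning(sprintf("element '%s' has zero reconstructed mass",
                    names(which(tot == 0))[1]))
  100 * mass / tot
}

## accessors -----------------------------------------------------------------

#' @rdname PMFSolution-class
#' @export
setMethod("profiles", "PMFSolution", function(x) x@profiles)

#' @rdname PMFSolution-class
#' @export
setMethod("contributions", "PMFSolution", function(x) x@contributions)

#' @rdname PMFSolution-class
#' @export
setMethod("qTrue", "PMFSolution", function(x) x@q_true)

#' @rdname PMFSolution-class
#' @export
setMethod("qRobust", "PMFSolution", function(x) x@q_robust)

#' @rdname PMFSolution-class
#' @export
setMethod("scaledResiduals", "PMFSolution", function(x) x@residuals / x@alpha)

#' @rdname PMFSolution-class
#' @export
setMethod("elementR2", "PMFSolution", function(x) x@r2)

#' @rdname PMFSolution-class
#' @export
setMethod("runTable", "PMFSolution", function(x) x@runs)

#' @rdname PMFSolution-class
#' @export
setMethod("residuals", "PMFSolution", function(object) object@residuals)

setMethod("show", "PMFSolution", function(object) {
  cat(sprintf("PMFSolution: %d factors, %d samples x %d elements\n",
              object@n_factors, nrow(object@contributions),
              ncol(object@profiles)))
  cat(sprintf("  Q(true) %.4g, Q(robust) %.4g, best-run seed %d (%s)\n",
              object@q_true, object@q_robust, object@run_seed,
              if (object@converged) "converged" else "not converged"))
  cat("  per-element R2:",
      paste(sprintf("%s %.3f", names(object@r2), object@r2), collapse = ", "),
      "\n")
  invisible(NULL)
})
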