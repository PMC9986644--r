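test_that("uncertainty rules reproduce the boundary cases exactly", {
  X <- matrix(c(0.6, 2, 1, 3), 2, 2,
              dimnames = list(NULL, c("Cd", "Pb")))
  u <- buildUncertainty(X, mdl = c(Cd = 1.2, Pb = 1), error_fraction = 0.05)
  expect_equal(unname(u$alpha[1, "Cd"]), 5 / 6 * 1.2)  # X = 0.5 MDL -> 1.0
  expect_equal(unname(u$alpha[1, "Cd"]), 1.0)
  expect_equal(unname(u$alpha[2, "Cd"]), 0.05 * 2 + 1.2)
  expect_equal(unname(u$alpha[1, "Pb"]), 5 / 6 * 1)    # X = MDL: <= rule
  expect_equal(unname(u$rule[1, "Pb"]), "below_mdl")
  expect_equal(unname(u$alpha[2, "Pb"]), 0.05 * 3 + 1)
  expect_true(all(u$alpha > 0))
  expect_error(buildUncertainty(X, mdl = c(Cd = 1.2)), "Pb")
  expect_error(buildUncertainty(X, mdl = c(Cd = 1.2, Pb = 1),
                                error_fraction = 0), "positive")
})

test_that("an exactly factorable matrix is fit to numerically zero Q", {
  set.seed(42)
  G0 <- matrix(runif(60, 0, 2), 30, 2)
  F0 <- matrix(runif(12, 0.5, 3), 2, 6)
  X <- G0 %*% F0
  colnames(X) <- pteElements()
  fit <- fitPMF(X, alpha = matrix(1, 30, 6), n_factors = 2, n_runs = 5,
                seed = 7)
  expect_lt(qTrue(fit), 1e-6 * length(X))
  expect_true(all(elementR2(fit) > 0.999))
  # reconstruction identity: G F + E == X exactly as stored
  expect_equal(contributions(fit) %*% profiles(fit) + residuals(fit), X,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Q is monotone non-increasing across iterations", {
  mix <- generateMixture(n_samples = 60, seed = 2, noise_fraction = 0.05)
  fit <- fitPMF(mix$samples, n_factors = 3, n_runs = 3, seed = 21)
  tr <- fit@q_trace
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) <= 1e-8 * pmax(tr[-length(tr)], 1)))
})

test_that("sample order is immaterial: permuting rows permutes G, Q unchanged", {
  mix <- generateMixture(n_samples = 40, seed = 5, noise_fraction = 0.05)
  u <- buildUncertainty(mix$samples)
  set.seed(55)
  G0 <- matrix(runif(40 * 3, 0.1, 2), 40, 3)
  F0 <- matrix(runif(3 * 6, 0.5, 20), 3, 6)
  fit <- fitPMF(mix$X, alpha = u$alpha, n_factors = 3,
                init = list(G = G0, F = F0))
  perm <- sample(nrow(mix$X))
  fit_p <- fitPMF(mix$X[perm, ], alpha = u$alpha[perm, ], n_factors = 3,
                  init = list(G = G0[perm, ], F = F0))
  # identical trajectory on the permuted problem: Q equal, G row-permuted
  expect_equal(qTrue(fit_p), qTrue(fit), tolerance = 1e-12)
  expect_equal(unname(contributions(fit_p)[order(perm), ]),
               unname(contributions(fit)), tolerance = 1e-9)
  expect_equal(unname(profiles(fit_p)), unname(profiles(fit)),
               tolerance = 1e-9)
})

test_that("same seed gives a bit-identical solution", {
  mix <- generateMixture(n_samples = 30, seed = 4, noise_fraction = 0.05)
  f1 <- fitPMF(mix$samples, n_factors = 3, n_runs = 2, seed = 33)
  f2 <- fitPMF(mix$samples, n_factors = 3, n_runs = 2, seed = 33)
  expect_identical(profiles(f1), profiles(f2))
  expect_identical(contributions(f1), contributions(f2))
  expect_identical(qTrue(f1), qTrue(f2))
})

test_that("robust Q caps outlying scaled residuals at the threshold", {
  mix <- generateMixture(n_samples = 30, seed = 6, noise_fraction = 0.05)
  fit <- fitPMF(mix$samples, n_factors = 3, n_runs = 2, seed = 13)
  # no residual beyond the cap: robust equals true
  expect_equal(robustQ(fit, outlier_threshold = Inf), qTrue(fit))
  expect_lte(robustQ(fit, 4), qTrue(fit))
  # hand check of the capping rule on a doctored solution
  sol <- fit
  sol@residuals[1, 1] <- 8 * sol@alpha[1, 1]   # scaled residual 8
  base <- sum(pmin(scaledResiduals(sol)[-1]^2, 16))
  expect_equal(robustQ(sol, 4), base + 16)     # contributes 16, not 64
  expect_error(robustQ(fit, 0), "positive")
})

test_that("factor contribution shares are percentages that sum to 100", {
  mix <- generateMixture(n_samples = 40, seed = 8, noise_fraction = 0.05)
  fit <- fitPMF(mix$samples, n_factors = 3, n_runs = 4, seed = 15)
  shares <- factorContributions(fit)
  expect_equal(unname(rowSums(shares)), rep(100, ncol(profiles(fit))))
  expect_true(all(shares >= 0))
  # two sources generating disjoint element blocks -> 100/0 splits;
  # a few single-source samples pin down the factorization (strictly
  # interior contributions leave a continuum of exact decompositions)
  F2 <- rbind(s1 = c(As = 2, Cd = 0, Pb = 1, Cr = 0),
              s2 = c(As = 0, Cd = 5, Pb = 0, Cr = 3))
  set.seed(1)
  G2 <- matrix(rlnorm(40), 20, 2)
  G2[1:2, 2] <- 0
  G2[3:4, 1] <- 0
  X2 <- G2 %*% F2
  fit2 <- fitPMF(X2, alpha = matrix(0.1, 20, 4), n_factors = 2,
                 n_runs = 6, seed = 3)
  sh2 <- factorContributions(fit2)
  for (el in colnames(F2))
    expect_equal(sort(unname(sh2[el, ])), c(0, 100), tolerance = 1e-3)
})

test_that("the factor-number elbow appears on noise-free rank-3 data", {
  mix <- generateMixture(n_samples = 80, seed = 10, noise_fraction = 0)
  alpha <- buildUncertainty(mix$samples)$alpha
  q3 <- qTrue(fitPMF(mix$X, alpha = alpha, n_factors = 3, n_runs = 4,
                     seed = 17))
  q2 <- qTrue(fitPMF(mix$X, alpha = alpha, n_factors = 2, n_runs = 4,
                     seed = 17))
  expect_lt(q3, q2 * 1e-3)
})

test_that("input validation rejects bad shapes and NaN", {
  X <- matrix(1:12, 4, 3, dimnames = list(NULL, c("As", "Cd", "Pb")))
  expect_error(fitPMF(X, alpha = matrix(1, 4, 3), n_factors = 1), "n_factors")
  expect_error(fitPMF(X, alpha = matrix(1, 4, 3), n_factors = 3), "n_factors")
  Xn <- X; Xn[1, 1] <- NA
  expect_error(fitPMF(Xn, alpha = matrix(1, 4, 3), n_factors = 2), "NA")
  expect_error(fitPMF(X, alpha = matrix(1, 2, 2), n_factors = 2), "match")
})
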