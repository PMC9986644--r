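# Shared fixtures built in code.

# A minimal well-formed table: three park-area samples whose As values
# reproduce the study-area PA mean (8.56) and range (3.32-13.9) exactly.
tinySamples <- function() {
  conc <- rbind(
    As = c(3.32, 8.46, 13.90),
    Cd = c(0.70, 0.85, 1.05),
    Pb = c(1.16, 6.78, 13.87),
    Cr = c(20.09, 38.85, 56.58),
    Ni = c(5.98, 12.99, 17.88),
    Cu = c(9.13, 15.64, 23.10))
  colnames(conc) <- paste0("PA_", 1:3)
  SoilSamples(conc, land_use = rep("PA", 3))
}

# Write a sample table CSV and return its path.
writeTinyCsv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "samples.csv")
  writeSampleTable(tinySamples(), path)
  path
}

# Best factor-to-source matching by cosine similarity of unit-sum profiles;
# returns the permutation applied to fitted factors.
matchFactors <- function(fitted_profiles, true_profiles) {
  a <- nrow(true_profiles)
  tp <- true_profiles / rowSums(true_profiles)
  perms <- asplit(as.matrix(expand.grid(rep(list(seq_len(a)), a))), 1)
  perms <- Filter(function(p) length(unique(p)) == a, perms)
  cosim <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  scores <- vapply(perms, function(p)
    sum(vapply(seq_len(a),
               function(i) cosim(fitted_profiles[p[i], ], tp[i, ]),
               numeric(1))), numeric(1))
  as.integer(perms[[which.max(scores)]])
}
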