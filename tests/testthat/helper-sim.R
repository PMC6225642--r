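# shared fixture builders and independent oracles

# small three-environment cross with an optional planted QTL
make_cross <- function(n_chr = 3, mpc = 10, len = 3e5, n_strains = 60,
                       seed = 1, missing_rate = 0) {
  map <- simulate_map(n_chr, mpc, len, seed = seed)
  simulate_segregants(map, n_strains, seed = seed + 1,
                      missing_rate = missing_rate)
}

env3 <- c(SB14_Sk = 0, M15_Sk = 2, M15 = 4)

# independent brute-force per-marker least-squares LOD oracle (lm() path,
# no shared code with the scan engine)
oracle_lods <- function(geno, pheno, trait, rank_transform = TRUE) {
  d <- pheno[pheno$trait == trait & !is.na(pheno$value), ]
  agg <- stats::aggregate(value ~ strain + environment, data = d, FUN = mean)
  agg <- agg[agg$strain %in% colnames(geno$calls), ]
  y <- agg$value
  if (rank_transform) {
    # within-environment mid-rank normal scores, written independently
    for (e in unique(agg$environment)) {
      i <- agg$environment == e
      y[i] <- qnorm((rank(y[i], ties.method = "average") - 0.5) / sum(i))
    }
  }
  e <- factor(agg$environment)
  P <- genotype_probabilities(geno)
  N <- length(y)
  out <- matrix(NA_real_, nrow(P), 2,
                dimnames = list(rownames(P), c("add", "full")))
  for (i in seq_len(nrow(P))) {
    g <- P[i, agg$strain]
    r0 <- sum(resid(lm(y ~ e))^2)
    ra <- sum(resid(lm(y ~ e + g))^2)
    rf <- sum(resid(lm(y ~ e + g + g:e))^2)
    out[i, ] <- (N / 2) * log10(c(r0 / ra, r0 / rf))
  }
  out
}

# recombination fraction between two marker rows of a calls matrix
recomb_fraction <- function(calls, i, j) {
  ok <- !is.na(calls[i, ]) & !is.na(calls[j, ])
  mean(calls[i, ok] != calls[j, ok])
}

# analytic crossing time of the logistic generator curve, found numerically
# (independent of the interpolation-based extractor)
logistic_crossing <- function(threshold, lag, rate, plateau, upper = 1e4) {
  uniroot(function(t) logistic_co2(t, lag, rate, plateau) - threshold,
          c(0, upper), tol = 1e-10)$root
}
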