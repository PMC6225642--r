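#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their mid-ranks,
#' `qnorm((rank - 0.5) / n)`, with average ranks for ties. Missing values stay
#' missing and do not affect the ranks of the others. Standard normalisation
#' applied to trait vectors before linkage analysis.
#'
#' @param x Numeric vector (>= 2 non-missing values).
#' @return Numeric vector of the same length.
#' @examples
#' rank_normal_transform(c(1, 2, 3))
#' @export
rank_normal_transform <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2) stop("need >= 2 non-missing values")
  if (length(unique(x[ok])) == 1) {
    warning("all values identical; transform maps them to 0")
    x[ok] <- 0
    return(x)
  }
  r <- rank(x, na.last = "keep", ties.method = "average")
  out <- stats::qnorm((r - 0.5) / n)
  out
}

# assemble replicate-level model frame for one trait
.pheno_frame <- function(pheno, trait, environments = NULL) {
  stopifnot(all(c("strain", "environment", "replicate", "trait", "value")
                %in% names(pheno)))
  d <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
  if (!is.null(environments)) {
    d <- d[d$environment %in% environments, , drop = FALSE]
    d$environment <- factor(d$environment, levels = environments)
  } else {
    d$environment <- factor(d$environment)
  }
  if (!nrow(d)) stop("no records for trait ", trait)
  d
}

#' Two-way variance decomposition of a phenotype table
#'
#' Fits the two-way fixed-effects model y = m + E + U + U*E + e by sequential
#' (type I) least squares, where E is the environment and U the chosen unit
#' factor: the cross (LM1), the strain (LM2) or a two-class QTL genotype
#' (LM3). Terms are entered in the order environment, unit, interaction, and
#' each term's share of the total sum of squares is reported; on a balanced
#' design the decomposition is order-invariant. P-values are classical F
#' tests by default; setting `n_perm > 0` replaces them with permutation
#' p-values (response values permuted, sequential SS recomputed).
#'
#' @param pheno Long phenotype table (`strain, environment, replicate, trait,
#'   value`).
#' @param trait Trait to decompose.
#' @param unit `"strain"`, `"cross"` or `"genotype"`.
#' @param cross Named character vector strain -> cross (required for
#'   `unit = "cross"`).
#' @param genotype Named character vector strain -> allele class (required for
#'   `unit = "genotype"`).
#' @param environments Optional subset/ordering of environments.
#' @param n_perm Number of permutations for permutation p-values (0 = F test).
#' @param seed Seed for the permutation p-values.
#' @return A `variance_decomposition`: data.frame with columns
#'   `model, term, df, ss, percent, p` (residual has `p = NA`); percents sum
#'   to 100. Attribute `"degenerate"` is TRUE when the total SS is zero.
#' @export
decompose_variance <- function(pheno, trait,
                               unit = c("strain", "cross", "genotype"),
                               cross = NULL, genotype = NULL,
                               environments = NULL,
                               n_perm = 0, seed = 1) {
  unit <- match.arg(unit)
  d <- .pheno_frame(pheno, trait, environments)
  u <- switch(unit,
    strain = d$strain,
    cross = {
      if (is.null(cross)) stop("unit = 'cross' needs a strain -> cross map")
      unname(cross[d$strain])
    },
    genotype = {
      if (is.null(genotype)) stop("unit = 'genotype' needs a strain -> allele map")
      unname(genotype[d$strain])
    }
  )
  keep <- !is.na(u)
  d <- d[keep, , drop = FALSE]
  u <- factor(u[keep])
  if (nlevels(u) < 2) stop("unit factor has fewer than 2 levels")
  if (nlevels(d$environment) < 2) stop("environment has fewer than 2 levels")
  model_tag <- switch(unit, strain = "LM2", cross = "LM1", genotype = "LM3")
  term_unit <- switch(unit, strain = "S", cross = "C", genotype = "Q")
  df <- data.frame(y = d$value, E = d$environment, U = u)
  tot <- sum((df$y - mean(df$y))^2)
  if (tot == 0) {
    out <- data.frame(
      model = model_tag,
      term = c("E", term_unit, paste0(term_unit, "*E"), "residual"),
      df = c(nlevels(df$E) - 1, nlevels(u) - 1, NA, NA),
      ss = 0, percent = 0, p = NA_real_
    )
    attr(out, "degenerate") <- TRUE
    class(out) <- c("variance_decomposition", "data.frame")
    return(out)
  }
  an <- stats::anova(stats::lm(y ~ E + U + E:U, data = df))
  ss <- an[["Sum Sq"]]
  p <- an[["Pr(>F)"]]
  if (n_perm > 0) {
    set.seed(seed)
    fstat <- an[["F value"]][seq_len(nrow(an) - 1)]
    exceed <- numeric(length(fstat))
    for (b in seq_len(n_perm)) {
      dp <- df
      dp$y <- sample(df$y)
      fp <- stats::anova(stats::lm(y ~ E + U + E:U, data = dp))[["F value"]]
      exceed <- exceed + (fp[seq_along(fstat)] >= fstat)
    }
    p <- c((exceed + 1) / (n_perm + 1), NA)
  }
  out <- data.frame(
    model = model_tag,
    term = c("E", term_unit, paste0(term_unit, "*E"), "residual"),
    df = an$Df, ss = ss, percent = 100 * ss / sum(ss), p = p
  )
  attr(out, "degenerate") <- FALSE
  class(out) <- c("variance_decomposition", "data.frame")
  out
}

#' Broad-sense heritability from replicate variance
#'
#' h2 = (sigmaP^2 - sigmaE^2) / sigmaP^2, where sigmaP^2 is the variance of
#' the progeny population (per-observation values, one environment) and
#' sigmaE^2 is the median over strains of the within-strain replicate
#' variance. The estimate is not clipped: values can be negative when the
#' replicate noise exceeds the population spread, and they are flagged.
#'
#' @param pheno Long phenotype table.
#' @param trait Trait name.
#' @param environment Environment in which to estimate.
#' @param strains Optional subset of strains (e.g. the progeny, excluding
#'   parents).
#' @return One-row data.frame: `trait, environment, sigma_P2, sigma_E2, h2,
#'   flagged` (flagged when h2 < 0 or undefined).
#' @export
heritability <- function(pheno, trait, environment, strains = NULL) {
  d <- .pheno_frame(pheno, trait, environment)
  if (!is.null(strains)) d <- d[d$strain %in% strains, , drop = FALSE]
  if (length(unique(d$strain)) < 2) stop("need >= 2 strains")
  reps <- tapply(d$value, d$strain, length)
  if (mean(reps >= 2) < 0.5) {
    stop("need >= 2 replicates for at least half the strains")
  }
  sigma_p2 <- stats::var(d$value)
  rv <- tapply(d$value, d$strain, stats::var)
  sigma_e2 <- stats::median(rv[!is.na(rv)])
  if (sigma_p2 == 0) {
    return(data.frame(
      trait = trait, environment = environment,
      sigma_P2 = 0, sigma_E2 = sigma_e2, h2 = NA_real_, flagged = TRUE
    ))
  }
  h2 <- (sigma_p2 - sigma_e2) / sigma_p2
  data.frame(
    trait = trait, environment = environment,
    sigma_P2 = sigma_p2, sigma_E2 = sigma_e2, h2 = h2, flagged = h2 < 0
  )
}

#' Transgression fraction of a progeny population
#'
#' A progeny clone is transgressive when its mean phenotype lies beyond the
#' higher parental mean plus `k` pooled parental replicate SDs, or below the
#' lower parental mean minus the same margin (direction-agnostic).
#'
#' @param progeny_means Named numeric vector of progeny strain means.
#' @param parent_a,parent_b Numeric vectors of parental replicate
#'   measurements.
#' @param k Margin in pooled parental SD units (default 2).
#' @return List: `percent` (of progeny transgressive), `n_transgressive`,
#'   `limits` (lower, upper), `pooled_sd`.
#' @export
transgression_fraction <- function(progeny_means, parent_a, parent_b, k = 2) {
  parent_a <- parent_a[!is.na(parent_a)]
  parent_b <- parent_b[!is.na(parent_b)]
  if (length(parent_a) < 2 || length(parent_b) < 2) {
    stop("both parents need >= 2 replicate measurements")
  }
  na <- length(parent_a); nb <- length(parent_b)
  pooled_sd <- sqrt(((na - 1) * stats::var(parent_a) +
    (nb - 1) * stats::var(parent_b)) / (na + nb - 2))
  mu <- sort(c(mean(parent_a), mean(parent_b)))
  lims <- c(lower = mu[1] - k * pooled_sd, upper = mu[2] + k * pooled_sd)
  x <- progeny_means[!is.na(progeny_means)]
  tg <- x < lims["lower"] | x > lims["upper"]
  list(
    percent = 100 * mean(tg), n_transgressive = sum(tg),
    limits = lims, pooled_sd = pooled_sd
  )
}

#' Euclidean phenotype distance between strains
#'
#' Builds a strain x condition matrix of mean trait values (one condition per
#' trait x environment), z-scores each condition across strains to prevent
#' scale effects, and returns pairwise Euclidean distances. With the
#' `kinetics_preset = "t80g"` option only `t80g` represents the (strongly
#' correlated) kinetic traits, the convention used when comparing whole
#' phenotypic profiles.
#'
#' @param pheno Long phenotype table.
#' @param traits Traits to include (default: all in the table).
#' @param environments Environments to include (default: all).
#' @param kinetics_preset `"all"` (keep every trait listed) or `"t80g"`
#'   (drop t35g/t50g/V15_50/V50_80, keeping t80g for kinetics).
#' @return A `dist`-convertible symmetric matrix with strain labels; strains
#'   missing any included condition are dropped. Zero-variance conditions are
#'   excluded with a warning.
#' @export
phenotype_distance <- function(pheno, traits = NULL, environments = NULL,
                               kinetics_preset = c("all", "t80g")) {
  kinetics_preset <- match.arg(kinetics_preset)
  d <- pheno[!is.na(pheno$value), , drop = FALSE]
  if (is.null(traits)) traits <- unique(d$trait)
  if (kinetics_preset == "t80g") {
    traits <- setdiff(traits, c("t35g", "t50g", "V15_50", "V50_80"))
  }
  if (is.null(environments)) environments <- unique(d$environment)
  d <- d[d$trait %in% traits & d$environment %in% environments, , drop = FALSE]
  agg <- stats::aggregate(
    value ~ strain + environment + trait, data = d, FUN = mean
  )
  agg$cond <- paste(agg$trait, agg$environment, sep = "|")
  m <- stats::reshape(
    agg[, c("strain", "cond", "value")],
    idvar = "strain", timevar = "cond", direction = "wide"
  )
  rn <- m$strain
  m <- as.matrix(m[, -1, drop = FALSE])
  rownames(m) <- rn
  keep_rows <- stats::complete.cases(m)
  m <- m[keep_rows, , drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance condition(s): ",
            paste(sub("^value\\.", "", colnames(m)[sds == 0]), collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  z <- scale(m)
  as.matrix(stats::dist(z))
}

#' Reaction norms of a trait across environments
#'
#' @param pheno Long phenotype table.
#' @param trait Trait name.
#' @param environments Environment ordering (default
#'   [default_environments()] intersected with the table).
#' @return Matrix strains x environments of replicate-mean values; strains
#'   with any missing environment are dropped.
#' @export
reaction_norms <- function(pheno, trait, environments = NULL) {
  if (is.null(environments)) {
    environments <- intersect(default_environments(), unique(pheno$environment))
    if (!length(environments)) environments <- unique(pheno$environment)
  }
  d <- .pheno_frame(pheno, trait, environments)
  mt <- tapply(d$value, list(d$strain, d$environment), mean)
  mt <- mt[, environments, drop = FALSE]
  mt[stats::complete.cases(mt), , drop = FALSE]
}

#' Correlation distance between reaction norms
#'
#' D_ij = |1 - corr(norm_i, norm_j)| over the per-environment mean values of
#' two strains, so parallel norms (correlation 1) are at distance 0 and
#' mirror-image norms (correlation -1) at distance 2. Edge rules for flat
#' norms (zero variance, correlation undefined): two flat norms are at
#' distance 0; a flat norm is at distance 1 from every varying norm.
#'
#' @param norms Matrix strains x environments ([reaction_norms()] output).
#' @return Symmetric matrix of distances in [0, 2], zero diagonal.
#' @export
reaction_norm_distance <- function(norms) {
  stopifnot(is.matrix(norms), ncol(norms) >= 2, nrow(norms) >= 2)
  v <- apply(norms, 1, stats::var)
  flat <- v == 0
  n <- nrow(norms)
  D <- matrix(0, n, n, dimnames = list(rownames(norms), rownames(norms)))
  if (any(!flat)) {
    cc <- suppressWarnings(stats::cor(t(norms[!flat, , drop = FALSE])))
    D[!flat, !flat] <- abs(1 - cc)
  }
  D[flat, !flat] <- 1
  D[!flat, flat] <- 1
  diag(D) <- 0
  D
}

#' Cluster reaction norms by partitioning around medoids
#'
#' Runs PAM on a precomputed distance matrix for each candidate number of
#' clusters and keeps the k with the best mean silhouette width. Silhouette
#' is undefined at k = 1, so the examined range starts at 2; when even the
#' best silhouette is below `sil_floor` the partition is considered
#' degenerate and a single cluster is reported with a flag.
#'
#' @param D Symmetric distance matrix (e.g. [reaction_norm_distance()]).
#' @param k_range Candidate cluster counts (default 2:10; truncated to n - 1).
#' @param sil_floor Mean-silhouette threshold below which the one-cluster
#'   fallback is reported (default 0.1).
#' @return A `norm_clustering` list: `k`, `clustering` (named integer vector),
#'   `silhouette` (named by k), `medoids`, `degenerate`.
#' @export
cluster_reaction_norms <- function(D, k_range = 2:10, sil_floor = 0.1) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), nrow(D) >= 3)
  n <- nrow(D)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("no admissible k in range")
  dd <- stats::as.dist(D)
  sil <- stats::setNames(numeric(length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    fit <- cluster::pam(dd, k = k_range[i], diss = TRUE)
    fits[[i]] <- fit
    sil[i] <- fit$silinfo$avg.width
  }
  best <- which.max(sil)
  degenerate <- sil[best] < sil_floor
  if (degenerate) {
    clustering <- stats::setNames(rep(1L, n), rownames(D))
    k <- 1L
    medoids <- rownames(D)[1]
  } else {
    clustering <- fits[[best]]$clustering
    k <- k_range[best]
    medoids <- fits[[best]]$medoids
  }
  structure(
    list(k = k, clustering = clustering, silhouette = sil,
         medoids = medoids, degenerate = degenerate),
    class = "norm_clustering"
  )
}

#' @export
print.norm_clustering <- function(x, ...) {
  cat("Reaction-norm clustering:", x$k, "cluster(s)",
      if (x$degenerate) "(degenerate fallback)" else "", "\n")
  print(table(cluster = x$clustering))
  invisible(x)
}

#' Ternary QTL-by-environment interaction profile
#'
#' Quantifies how much of a QTL's action is a constant genetic effect versus
#' interaction with each of the two environmental axes of the three-condition
#' design. Three two-way ANOVAs (allele, environment, interaction) are fitted:
#' on the grape-must pair (SB14_Sk vs M15_Sk), on the micro-oxygenation pair
#' (M15_Sk vs M15), and on all three conditions. Each percentage of variance
#' is computed with the environment sum of squares removed from the
#' denominator, so conditions with a huge E main effect remain comparable;
#' the three percentages (Q x E on the GM pair, Q x E on the u-Ox pair, Q on
#' all conditions) renormalised to sum 1 give the ternary coordinates.
#'
#' @param pheno Long phenotype table.
#' @param trait Trait name.
#' @param genotype Named character vector strain -> allele class at the locus.
#' @param env_gm Environments of the grape-must contrast.
#' @param env_uox Environments of the micro-oxygenation contrast.
#' @param env_all All environments for the overall genetic effect.
#' @param alpha Significance level of the flags (default 0.05).
#' @return One-row data.frame: `g, gm, uox` (ternary proportions summing to
#'   1), `pct_g, pct_gm, pct_uox` (the raw environment-free percentages) and
#'   logical `sig_g, sig_gm, sig_uox`.
#' @export
qtl_interaction_profile <- function(pheno, trait, genotype,
                                    env_gm = c("SB14_Sk", "M15_Sk"),
                                    env_uox = c("M15_Sk", "M15"),
                                    env_all = default_environments(),
                                    alpha = 0.05) {
  if (length(unique(genotype[!is.na(genotype)])) < 2) {
    stop("monomorphic locus")
  }
  one <- function(envs, term) {
    dec <- decompose_variance(pheno, trait,
      unit = "genotype", genotype = genotype, environments = envs
    )
    ss <- stats::setNames(dec$ss, dec$term)
    denom <- sum(ss) - ss[["E"]]
    pct <- 100 * ss[[term]] / denom
    list(pct = pct, p = dec$p[dec$term == term])
  }
  g <- one(env_all, "Q")
  gm <- one(env_gm, "Q*E")
  uox <- one(env_uox, "Q*E")
  raw <- c(g = g$pct, gm = gm$pct, uox = uox$pct)
  prop <- raw / sum(raw)
  data.frame(
    g = prop[["g"]], gm = prop[["gm"]], uox = prop[["uox"]],
    pct_g = raw[["g"]], pct_gm = raw[["gm"]], pct_uox = raw[["uox"]],
    sig_g = g$p < alpha, sig_gm = gm$p < alpha, sig_uox = uox$p < alpha
  )
}
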