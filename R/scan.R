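#' Filter markers for 1:1 segregation and even spacing
#'
#' Removes markers whose A:B counts fail a 1-df chi-square test of 1:1
#' segregation at level `alpha` (p <= alpha removed), then thins the
#' survivors so adjacent retained markers on a chromosome are at least
#' `min_spacing` base pairs apart. When two markers are closer than the
#' spacing, the one with fewer missing calls is kept (ties go to the
#' leftmost).
#'
#' @param geno A `geno_matrix`.
#' @param alpha Significance level of the segregation test (default 0.05).
#' @param min_spacing Minimum spacing in bp (default 0 = no thinning).
#' @return A `geno_matrix` restricted to the retained markers.
#' @export
filter_markers <- function(geno, alpha = 0.05, min_spacing = 0) {
  stopifnot(inherits(geno, "geno_matrix"))
  nA <- rowSums(geno$calls == "A", na.rm = TRUE)
  nB <- rowSums(geno$calls == "B", na.rm = TRUE)
  n <- nA + nB
  x2 <- ifelse(n > 0, (nA - nB)^2 / n, Inf)
  p <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  keep <- p > alpha
  if (min_spacing > 0) {
    nmiss <- rowSums(is.na(geno$calls))
    for (ch in unique(geno$map$chrom)) {
      idx <- which(geno$map$chrom == ch & keep)
      if (length(idx) < 2) next
      last <- idx[1]
      for (i in idx[-1]) {
        if (geno$map$pos[i] - geno$map$pos[last] < min_spacing) {
          if (nmiss[i] < nmiss[last]) {
            keep[last] <- FALSE
            last <- i
          } else {
            keep[i] <- FALSE
          }
        } else {
          last <- i
        }
      }
    }
  }
  if (!any(keep)) stop("all markers removed by filtering")
  out <- list(
    map = .check_map(geno$map[keep, , drop = FALSE]),
    calls = geno$calls[keep, , drop = FALSE]
  )
  class(out) <- "geno_matrix"
  out
}

#' Conditional genotype probabilities at typed and missing markers
#'
#' Computes P(allele A) for every marker x strain cell. Observed calls give
#' probability 0 or 1. Missing calls are inferred from the nearest informative
#' flanking markers on the chromosome via the Haldane recombination fractions
#' implied by the cM distances: with both flanks typed,
#' P(A | flanks) is the two-locus path probability (e.g. both flanks A:
#' (1-r1)(1-r2) / [(1-r1)(1-r2) + r1 r2]); with a single informative flank the
#' one-flank formula (1-r or r) applies; with no informative marker on the
#' chromosome the probability is 0.5. These probabilities are the regression
#' covariates of the Haley-Knott scan.
#'
#' @param geno A `geno_matrix`.
#' @return Numeric matrix (markers x strains) of P(A).
#' @export
genotype_probabilities <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  map <- geno$map
  calls <- geno$calls
  cmkb <- attr(map, "cm_per_kb")
  P <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    cm <- .pos_to_cm(map$pos[idx] - map$pos[idx][1], cmkb)
    for (s in seq_len(ncol(calls))) {
      g <- calls[idx, s]
      x <- ifelse(g == "A", 1, 0) # NA propagates
      typed <- which(!is.na(x))
      p <- as.numeric(x)
      if (length(typed) < length(idx)) {
        for (i in which(is.na(x))) {
          lt <- typed[typed < i]
          rt <- typed[typed > i]
          l <- if (length(lt)) lt[length(lt)] else NA_integer_
          r <- if (length(rt)) rt[1] else NA_integer_
          # absent flank handled as an uninformative one (r = 0.5)
          r1 <- if (is.na(l)) 0.5 else haldane(cm[i] - cm[l])
          r2 <- if (is.na(r)) 0.5 else haldane(cm[r] - cm[i])
          xl <- if (is.na(l)) 1 else x[l]
          xr <- if (is.na(r)) 1 else x[r]
          wA <- (if (xl == 1) 1 - r1 else r1) * (if (xr == 1) 1 - r2 else r2)
          wB <- (if (xl == 1) r1 else 1 - r1) * (if (xr == 1) r2 else 1 - r2)
          p[i] <- wA / (wA + wB)
        }
      }
      P[idx, s] <- p
    }
  }
  P
}

# Haley-Knott LOD engine.
# G: N x M matrix of genotype probabilities per observation;
# y: response; env: factor (or NULL / single level for single-environment).
# Returns list(lod_additive, lod_full, lod_interaction) of length M.
# LOD = (N/2) log10(RSS_reduced / RSS_model).
.hk_lods <- function(G, y, env = NULL) {
  N <- length(y)
  multi <- !is.null(env) && nlevels(droplevels(env)) >= 2
  if (multi) {
    env <- droplevels(env)
    X0 <- stats::model.matrix(~env)
    Dm <- X0[, -1, drop = FALSE]
  } else {
    X0 <- matrix(1, N, 1)
    Dm <- NULL
  }
  qr0 <- qr(X0)
  yt <- qr.resid(qr0, y)
  rss0 <- sum(yt^2)
  Gt <- qr.resid(qr0, G)
  gg <- colSums(Gt^2)
  gy <- colSums(Gt * yt)
  tol <- 1e-10 * max(gg, 1)
  mono <- gg <= tol
  rss_add <- rss0 - ifelse(mono, 0, gy^2 / pmax(gg, tol))
  rss_add <- pmax(rss_add, 0)
  if (!multi) {
    rss_full <- rss_add
  } else {
    k <- ncol(Dm) + 1L
    W <- vector("list", k)
    W[[1]] <- Gt
    for (j in seq_len(ncol(Dm))) W[[j + 1]] <- qr.resid(qr0, G * Dm[, j])
    B <- vapply(W, function(w) colSums(w * yt), numeric(ncol(G)))
    if (ncol(G) == 1) B <- matrix(B, 1)
    Sq <- matrix(0, ncol(G), k * (k + 1) / 2)
    ii <- 0
    sidx <- matrix(0L, k, k)
    for (a in seq_len(k)) {
      for (b in a:k) {
        ii <- ii + 1
        Sq[, ii] <- colSums(W[[a]] * W[[b]])
        sidx[a, b] <- sidx[b, a] <- ii
      }
    }
    qf <- rep(NA_real_, ncol(G))
    if (k == 3) {
      s11 <- Sq[, sidx[1, 1]]; s12 <- Sq[, sidx[1, 2]]; s13 <- Sq[, sidx[1, 3]]
      s22 <- Sq[, sidx[2, 2]]; s23 <- Sq[, sidx[2, 3]]; s33 <- Sq[, sidx[3, 3]]
      A11 <- s22 * s33 - s23^2
      A12 <- s13 * s23 - s12 * s33
      A13 <- s12 * s23 - s13 * s22
      A22 <- s11 * s33 - s13^2
      A23 <- s12 * s13 - s11 * s23
      A33 <- s11 * s22 - s12^2
      det <- s11 * A11 + s12 * A12 + s13 * A13
      scale3 <- pmax(s11, tol) * pmax(s22, tol) * pmax(s33, tol)
      ok <- det > 1e-9 * scale3
      b1 <- B[, 1]; b2 <- B[, 2]; b3 <- B[, 3]
      qf[ok] <- ((b1^2 * A11 + b2^2 * A22 + b3^2 * A33 +
        2 * (b1 * b2 * A12 + b1 * b3 * A13 + b2 * b3 * A23)) / det)[ok]
    } else if (k == 2) {
      s11 <- Sq[, sidx[1, 1]]; s12 <- Sq[, sidx[1, 2]]; s22 <- Sq[, sidx[2, 2]]
      det <- s11 * s22 - s12^2
      ok <- det > 1e-9 * pmax(s11, tol) * pmax(s22, tol)
      qf[ok] <- ((B[, 1]^2 * s22 - 2 * B[, 1] * B[, 2] * s12 +
        B[, 2]^2 * s11) / det)[ok]
    } else {
      ok <- rep(FALSE, ncol(G))
    }
    # rank-deficient (or k > 3) markers: pivoted QR fallback
    for (m in which(!ok)) {
      Wm <- do.call(cbind, lapply(W, function(w) w[, m]))
      if (max(abs(Wm)) <= sqrt(tol)) {
        qf[m] <- 0
      } else {
        qf[m] <- rss0 - sum(qr.resid(qr(Wm), yt)^2)
      }
    }
    rss_full <- pmax(rss0 - qf, 0)
  }
  rss_full <- pmin(rss_full, rss_add)
  floor_rss <- 1e-12 * rss0
  lod_add <- ifelse(rss_add <= floor_rss, Inf,
                    (N / 2) * log10(rss0 / rss_add))
  lod_full <- ifelse(rss_full <= floor_rss, Inf,
                     (N / 2) * log10(rss0 / rss_full))
  lod_add <- pmax(lod_add, 0)
  lod_full <- pmax(lod_full, lod_add)
  list(
    lod_additive = lod_add, lod_full = lod_full,
    lod_interaction = lod_full - lod_add
  )
}

# assemble the scan observations: strain x environment replicate means
.scan_obs <- function(geno, pheno, trait, environments, rank_transform,
                      transform_scope = "environment") {
  d <- .pheno_frame(pheno, trait, environments)
  strains <- intersect(colnames(geno$calls), unique(d$strain))
  if (length(strains) < 4) stop("fewer than 4 genotyped, phenotyped strains")
  d <- d[d$strain %in% strains, , drop = FALSE]
  agg <- stats::aggregate(value ~ strain + environment, data = d, FUN = mean)
  y_raw <- agg$value
  y <- y_raw
  if (rank_transform) {
    if (transform_scope == "environment") {
      # transform within each environment: preserves the comparability of
      # allele effects across conditions (a pooled transform would compress
      # them unevenly and manufacture spurious QTL x E interaction)
      y <- stats::ave(y_raw, agg$environment, FUN = rank_normal_transform)
    } else {
      y <- rank_normal_transform(y_raw)
    }
  }
  list(
    strains = strains,
    strain_idx = match(agg$strain, strains),
    env = droplevels(factor(agg$environment)),
    y = y, y_raw = y_raw
  )
}

#' Multi-environment Haley-Knott QTL scan
#'
#' Regresses a (rank-normal transformed) trait on conditional genotype
#' probabilities at every marker, with environment as additive and
#' interactive covariate. Observations are strain x environment replicate
#' means. At each marker three nested least-squares models are compared:
#' null (intercept + environment), additive (+ genotype probability) and
#' full (+ genotype x environment); the scan records
#' `lod_additive` = (N/2) log10(RSS_null / RSS_additive),
#' `lod_full` = (N/2) log10(RSS_null / RSS_full) and their difference
#' `lod_interaction`, with N the number of observations. With a single
#' environment the E terms drop and the additive and full models coincide.
#'
#' @param geno A `geno_matrix`.
#' @param pheno Long phenotype table.
#' @param trait Trait to scan.
#' @param environments Environments to use (default: all in the table).
#' @param rank_transform Apply [rank_normal_transform()] to the trait before
#'   scanning (default TRUE).
#' @param transform_scope `"environment"` (default) transforms within each
#'   environment, keeping allele effects comparable across conditions;
#'   `"stacked"` transforms the pooled vector, which mixes the environment
#'   main effect into the ranks and can distort QTL x E contrasts.
#' @return A `qtl_scan` object: list with `result` (data.frame `marker,
#'   chrom, pos, lod_additive, lod_full, lod_interaction`), `trait`,
#'   `environments`, `n_obs`, and the fitted engine state reused by
#'   [permutation_thresholds()] and [call_qtls()].
#' @seealso [permutation_thresholds()], [call_qtls()], [plot.qtl_scan()]
#' @export
scan_qtl <- function(geno, pheno, trait, environments = NULL,
                     rank_transform = TRUE,
                     transform_scope = c("environment", "stacked")) {
  stopifnot(inherits(geno, "geno_matrix"))
  transform_scope <- match.arg(transform_scope)
  obs <- .scan_obs(geno, pheno, trait, environments, rank_transform,
                   transform_scope)
  P <- genotype_probabilities(geno)[, obs$strains, drop = FALSE]
  G <- t(P)[obs$strain_idx, , drop = FALSE]
  lods <- .hk_lods(G, obs$y, obs$env)
  res <- data.frame(
    marker = geno$map$marker, chrom = geno$map$chrom, pos = geno$map$pos,
    lod_additive = lods$lod_additive, lod_full = lods$lod_full,
    lod_interaction = lods$lod_interaction,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      result = res, trait = trait,
      environments = levels(obs$env), n_obs = length(obs$y),
      rank_transform = rank_transform,
      engine = list(P = P, obs = obs, map = geno$map)
    ),
    class = "qtl_scan"
  )
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat("Haley-Knott scan:", x$trait, "|", nrow(x$result), "markers |",
      x$n_obs, "observations |",
      if (length(x$environments) > 1) {
        paste(length(x$environments), "environments")
      } else "single environment", "\n")
  top <- x$result[which.max(x$result$lod_full), ]
  cat(sprintf(
    "  top marker %s: LOD(add) = %.2f, LOD(full) = %.2f, LOD(int) = %.2f\n",
    top$marker, top$lod_additive, top$lod_full, top$lod_interaction
  ))
  invisible(x)
}

#' @param object,x A `qtl_scan`.
#' @param n Number of top markers to show.
#' @param ... Unused.
#' @rdname scan_qtl
#' @export
summary.qtl_scan <- function(object, n = 5, ...) {
  res <- object$result[order(-object$result$lod_full), ]
  cat("Trait:", object$trait, "- top", n, "markers by full-model LOD\n")
  print(utils::head(res, n), row.names = FALSE, digits = 4)
  invisible(res)
}

#' Plot LOD curves along the genome
#'
#' Draws the additive and full-model LOD profiles per chromosome, with
#' optional threshold lines.
#'
#' @param x A `qtl_scan`.
#' @param thresholds Optional [permutation_thresholds()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.qtl_scan <- function(x, thresholds = NULL, ...) {
  res <- x$result
  chroms <- unique(res$chrom)
  offs <- c(0, cumsum(tapply(res$pos, factor(res$chrom, chroms), max)))
  xpos <- res$pos + offs[match(res$chrom, chroms)]
  graphics::plot(xpos, res$lod_full,
    type = "l", col = "grey40", xlab = "genome position (bp)",
    ylab = "LOD", main = x$trait, ...
  )
  graphics::lines(xpos, res$lod_additive, col = "steelblue")
  if (!is.null(thresholds)) {
    graphics::abline(h = thresholds$additive, col = "steelblue", lty = 2)
    graphics::abline(h = thresholds$full, col = "grey40", lty = 2)
  }
  graphics::abline(v = offs[-1], col = "grey85")
  invisible(x)
}

#' Genome-wide permutation LOD thresholds
#'
#' Churchill-Doerge permutation test: strain identities are permuted against
#' the genotype columns, keeping each strain's environment block intact (so
#' the environment main effect and within-strain structure survive under the
#' null); for each permutation the genome-wide maximum LOD is recorded per
#' model, and the threshold is the (1 - alpha) quantile of those maxima.
#'
#' @param scan A fitted [scan_qtl()] object.
#' @param n_perm Number of permutations (>= 1; 1000 for production scans,
#'   the value behind a 5% genome-wide threshold).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param seed Integer seed; thresholds are reproducible per seed.
#' @return A `perm_thresholds` list: `additive`, `full`, `interaction`
#'   (thresholds), `max_lods` (n_perm x 3 matrix), `n_perm`, `alpha`, `seed`.
#' @export
permutation_thresholds <- function(scan, n_perm = 1000, alpha = 0.05, seed) {
  stopifnot(inherits(scan, "qtl_scan"), n_perm >= 1, alpha > 0, alpha <= 1)
  set.seed(seed)
  obs <- scan$engine$obs
  P <- scan$engine$P
  n_strains <- length(obs$strains)
  mx <- matrix(NA_real_, n_perm, 3,
               dimnames = list(NULL, c("additive", "full", "interaction")))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n_strains)
    G <- t(P)[perm[obs$strain_idx], , drop = FALSE]
    lods <- .hk_lods(G, obs$y, obs$env)
    mx[b, ] <- c(
      max(lods$lod_additive), max(lods$lod_full), max(lods$lod_interaction)
    )
  }
  thr <- apply(mx, 2, stats::quantile, probs = 1 - alpha, names = FALSE,
               type = 7)
  structure(
    list(
      additive = thr[["additive"]], full = thr[["full"]],
      interaction = thr[["interaction"]],
      max_lods = mx, n_perm = n_perm, alpha = alpha, seed = seed
    ),
    class = "perm_thresholds"
  )
}

#' @export
print.perm_thresholds <- function(x, ...) {
  cat(sprintf(
    "Genome-wide LOD thresholds (%d permutations, alpha = %.3g):\n  additive %.3f | full %.3f | interaction %.3f\n",
    x$n_perm, x$alpha, x$additive, x$full, x$interaction
  ))
  invisible(x)
}

# F-test p-value of the QTL (+ interaction) terms at one marker
.peak_p <- function(g, y, env, full_model) {
  multi <- !is.null(env) && nlevels(droplevels(env)) >= 2
  if (multi && full_model) {
    f0 <- stats::lm(y ~ env)
    f1 <- stats::lm(y ~ env + g + g:env)
  } else if (multi) {
    f0 <- stats::lm(y ~ env)
    f1 <- stats::lm(y ~ env + g)
  } else {
    f0 <- stats::lm(y ~ 1)
    f1 <- stats::lm(y ~ g)
  }
  a <- stats::anova(f0, f1)
  list(p = a[["Pr(>F)"]][2], coef = stats::coef(f1)[["g"]])
}

#' Call QTLs from a scan and its permutation thresholds
#'
#' Markers exceeding the additive or full-model threshold are grouped into
#' loci by single-linkage chaining along the chromosome with a gap tolerance
#' of `peak_window`; within each locus the peak is the marker with the
#' highest full-model LOD in its window. A locus is typed `"I"`
#' (interactive) when the interaction LOD at the peak exceeds the
#' interaction threshold, `"A"` (additive) otherwise. The allele raising the
#' trait, a model-vs-null F-test p-value and the percentage of variance
#' explained are evaluated at the peak marker.
#'
#' @param scan A [scan_qtl()] object.
#' @param thresholds A [permutation_thresholds()] object.
#' @param peak_window Window in bp for grouping and peak search (default
#'   30000, inclusive bounds).
#' @return data.frame of calls: `trait, chrom, pos, marker, lod, type,
#'   favorable_parent, pct_var, p, threshold` (empty when nothing exceeds
#'   the thresholds). `favorable_parent` is the allele class (A/B) with the
#'   higher trait value; map it through a trait-direction table for
#'   desirability.
#' @export
call_qtls <- function(scan, thresholds, peak_window = 30000) {
  stopifnot(inherits(scan, "qtl_scan"), inherits(thresholds, "perm_thresholds"))
  res <- scan$result
  sig <- res$lod_additive > thresholds$additive |
    res$lod_full > thresholds$full
  empty <- data.frame(
    trait = character(), chrom = character(), pos = integer(),
    marker = character(), lod = numeric(), type = character(),
    favorable_parent = character(), pct_var = numeric(), p = numeric(),
    threshold = numeric(), stringsAsFactors = FALSE
  )
  if (!any(sig)) return(empty)
  obs <- scan$engine$obs
  P <- scan$engine$P
  calls <- list()
  for (ch in unique(res$chrom[sig])) {
    idx <- which(sig & res$chrom == ch)
    pos <- res$pos[idx]
    grp <- cumsum(c(1, diff(pos) > peak_window))
    for (gi in unique(grp)) {
      members <- idx[grp == gi]
      peak <- members[which.max(res$lod_full[members])]
      is_int <- res$lod_interaction[peak] > thresholds$interaction
      g <- t(P)[obs$strain_idx, peak]
      pk <- .peak_p(g, obs$y, obs$env, full_model = is_int)
      # effect sign on the raw (untransformed) scale for interpretability
      sgn <- .peak_p(g, obs$y_raw, obs$env, full_model = is_int)$coef
      dec <- .marker_pct_var(g, obs$y_raw, obs$env, is_int)
      calls[[length(calls) + 1]] <- data.frame(
        trait = scan$trait, chrom = ch, pos = res$pos[peak],
        marker = res$marker[peak],
        lod = if (is_int) res$lod_full[peak] else res$lod_additive[peak],
        type = if (is_int) "I" else "A",
        favorable_parent = if (sgn >= 0) "A" else "B",
        pct_var = dec, p = pk$p,
        threshold = if (is_int) thresholds$full else thresholds$additive,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, calls)
  out[order(out$chrom, out$pos), ]
}

# % of total SS attributed to the genotype (+ genotype:environment) terms
.marker_pct_var <- function(g, y, env, include_interaction) {
  multi <- !is.null(env) && nlevels(droplevels(env)) >= 2
  if (multi) {
    an <- stats::anova(stats::lm(y ~ env + g + env:g))
    ss <- stats::setNames(an[["Sum Sq"]], rownames(an))
    q <- ss[["g"]] + if (include_interaction) ss[["env:g"]] else 0
  } else {
    an <- stats::anova(stats::lm(y ~ g))
    ss <- stats::setNames(an[["Sum Sq"]], rownames(an))
    q <- ss[["g"]]
  }
  100 * q / sum(ss)
}

#' Percentage of phenotypic variance explained by a QTL
#'
#' Two-way ANOVA of the trait on environment and the genotype at the locus
#' across all environments; the reported percentage is the genotype sum of
#' squares (plus the genotype-by-environment sum of squares for interactive
#' QTLs) over the total.
#'
#' @param geno A `geno_matrix`.
#' @param pheno Long phenotype table.
#' @param trait Trait name.
#' @param marker Marker ID of the locus.
#' @param include_interaction Add the QxE sum of squares (for type-I QTLs).
#' @param environments Optional environment subset.
#' @return Percentage of total variance (scalar).
#' @export
qtl_variance_explained <- function(geno, pheno, trait, marker,
                                   include_interaction = FALSE,
                                   environments = NULL) {
  stopifnot(marker %in% rownames(geno$calls))
  gt <- geno$calls[marker, ]
  if (length(unique(gt[!is.na(gt)])) < 2) stop("monomorphic locus")
  d <- .pheno_frame(pheno, trait, environments)
  d <- d[d$strain %in% names(gt)[!is.na(gt)], , drop = FALSE]
  g <- factor(gt[d$strain])
  .marker_pct_var(g, d$value, d$environment, include_interaction)
}

#' Merge kinetic-trait QTL calls into unique loci
#'
#' The CO2 kinetics traits are strongly correlated, so peaks for different
#' kinetic traits within `window` bp of one another are treated as one locus,
#' assigned to the trait with the lowest p-value. Grouping is single-linkage
#' along the chromosome. Calls for non-kinetic traits pass through untouched.
#'
#' @param calls data.frame of QTL calls ([call_qtls()] output, possibly
#'   stacked across traits) with a `p` column.
#' @param window Merge window in bp (default 10000).
#' @param kinetic_traits The trait set subject to merging.
#' @return data.frame of merged calls.
#' @export
merge_kinetics_qtls <- function(calls, window = 10000,
                                kinetic_traits = c("t35g", "t50g", "t80g",
                                                   "V15_50", "V50_80")) {
  if (!nrow(calls)) return(calls)
  kin <- calls$trait %in% kinetic_traits
  keep <- calls[!kin, , drop = FALSE]
  k <- calls[kin, , drop = FALSE]
  if (nrow(k)) {
    merged <- list()
    for (ch in unique(k$chrom)) {
      kc <- k[k$chrom == ch, , drop = FALSE]
      kc <- kc[order(kc$pos), , drop = FALSE]
      grp <- cumsum(c(1, diff(kc$pos) > window))
      for (gi in unique(grp)) {
        block <- kc[grp == gi, , drop = FALSE]
        merged[[length(merged) + 1]] <- block[which.min(block$p), , drop = FALSE]
      }
    }
    keep <- rbind(keep, do.call(rbind, merged))
  }
  out <- keep[order(keep$chrom, keep$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Colocalized QTLs between two crosses
#'
#' Reports pairs of calls affecting the same trait whose peak positions lie
#' within `window` bp of each other (inclusive), the criterion for a locus
#' shared by two independent crosses.
#'
#' @param calls1,calls2 QTL call tables from the two crosses.
#' @param window Colocalization window in bp (default 20000).
#' @return data.frame: `trait, chrom, pos1, marker1, pos2, marker2, distance`.
#' @export
colocalize <- function(calls1, calls2, window = 20000) {
  out <- data.frame(
    trait = character(), chrom = character(), pos1 = integer(),
    marker1 = character(), pos2 = integer(), marker2 = character(),
    distance = integer(), stringsAsFactors = FALSE
  )
  if (!nrow(calls1) || !nrow(calls2)) return(out)
  for (i in seq_len(nrow(calls1))) {
    hit <- calls2$trait == calls1$trait[i] &
      calls2$chrom == calls1$chrom[i] &
      abs(calls2$pos - calls1$pos[i]) <= window
    for (j in which(hit)) {
      out <- rbind(out, data.frame(
        trait = calls1$trait[i], chrom = calls1$chrom[i],
        pos1 = calls1$pos[i], marker1 = calls1$marker[i],
        pos2 = calls2$pos[j], marker2 = calls2$marker[j],
        distance = abs(calls2$pos[j] - calls1$pos[i]),
        stringsAsFactors = FALSE
      ))
    }
  }
  out
}
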