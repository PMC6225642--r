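#' Recompute the headline statistics of a published cross dataset
#'
#' End-to-end driver for a real segregant dataset distributed as two TSV
#' exports: a long phenotype table (strain x environment x replicate x trait)
#' and a genotype matrix for one cross. It recomputes, with this package's
#' estimators, the quantities usually reported for such designs:
#' \itemize{
#'   \item per-trait LM2 variance decompositions (environment / strain /
#'     strain-by-environment / residual percentages);
#'   \item broad-sense heritability per trait x environment and the fraction
#'     of combinations with h2 > 0.5;
#'   \item parental Euclidean phenotype distances (z-scored conditions,
#'     t80g-only kinetics preset);
#'   \item reaction-norm clustering per trait (PAM, best silhouette in 2..10);
#'   \item optionally, a full multi-environment QTL scan with permutation
#'     thresholds and QTL calls for every trait.
#' }
#'
#' @param pheno_path Long-format phenotype TSV (see [read_phenotypes()]).
#' @param geno_path Genotype matrix TSV for the cross (see
#'   [read_genotypes()]); `NULL` skips the scan.
#' @param parents Optional character vector of length 2 naming the parental
#'   strains in the phenotype table (for distances/transgression context).
#' @param traits Traits to analyse (default: all in the table).
#' @param n_perm Permutations per scan (default 1000).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param seed Seed for the permutation thresholds.
#' @return List with elements `lm2` (named list of variance decompositions),
#'   `heritability` (data.frame), `h2_over_0.5` (fraction), `parental_distance`
#'   (scalar or NA), `clusters` (named list of `norm_clustering`), and — when
#'   `geno_path` is given — `scans`, `thresholds`, `calls` (merged across
#'   kinetic traits).
#' @export
reproduce_published_analysis <- function(pheno_path, geno_path = NULL,
                                         parents = NULL, traits = NULL,
                                         n_perm = 1000, alpha = 0.05,
                                         seed = 1) {
  pheno <- read_phenotypes(pheno_path)
  if (is.null(traits)) traits <- unique(pheno$trait)
  envs <- intersect(default_environments(), unique(pheno$environment))
  if (length(envs) < 2) envs <- unique(pheno$environment)

  lm2 <- lapply(stats::setNames(traits, traits), function(tr) {
    decompose_variance(pheno, tr, unit = "strain", environments = envs)
  })

  her <- do.call(rbind, lapply(traits, function(tr) {
    do.call(rbind, lapply(envs, function(e) {
      tryCatch(heritability(pheno, tr, e), error = function(err) NULL)
    }))
  }))
  h2_frac <- mean(her$h2 > 0.5, na.rm = TRUE)

  pd <- NA_real_
  if (!is.null(parents) && length(parents) == 2 &&
      all(parents %in% pheno$strain)) {
    D <- phenotype_distance(pheno, kinetics_preset = "t80g")
    if (all(parents %in% rownames(D))) pd <- D[parents[1], parents[2]]
  }

  clusters <- lapply(stats::setNames(traits, traits), function(tr) {
    norms <- tryCatch(reaction_norms(pheno, tr, envs),
                      error = function(e) NULL)
    if (is.null(norms) || nrow(norms) < 3) return(NULL)
    cluster_reaction_norms(reaction_norm_distance(norms))
  })

  out <- list(
    lm2 = lm2, heritability = her, h2_over_0.5 = h2_frac,
    parental_distance = pd, clusters = clusters
  )

  if (!is.null(geno_path)) {
    geno <- filter_markers(read_genotypes(geno_path), alpha = 0.05)
    scans <- list(); thrs <- list(); calls <- list()
    for (tr in traits) {
      sc <- scan_qtl(geno, pheno, tr, environments = envs)
      th <- permutation_thresholds(sc, n_perm = n_perm, alpha = alpha,
                                   seed = seed)
      scans[[tr]] <- sc
      thrs[[tr]] <- th
      calls[[tr]] <- call_qtls(sc, th)
    }
    all_calls <- do.call(rbind, calls)
    out$scans <- scans
    out$thresholds <- thrs
    out$calls <- merge_kinetics_qtls(all_calls)
  }
  out
}
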