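#' Simulate segregant genotypes from a biparental cross
#'
#' Each simulated strain is a fully homozygous meiotic segregant of a cross
#' between two homozygous diploid parents, so genotypes take two classes,
#' `"A"` (first parent) and `"B"` (second parent) — equivalent to haploid
#' coding. Along each chromosome the parental origin switches between adjacent
#' markers with the Haldane recombination fraction implied by the physical
#' distance and the map's cM/kb rate (a no-interference crossover model).
#' Chromosomes segregate independently and the first marker of each chromosome
#' is A or B with probability 1/2, giving ~1:1 marginal segregation.
#'
#' @param map A `genetic_map` (see [simulate_map()]).
#' @param n_strains Number of segregants (>= 1).
#' @param seed Integer seed.
#' @param missing_rate Fraction of calls independently masked to `NA`
#'   (default 0), to exercise genotype-probability imputation.
#' @param strain_prefix Prefix for generated strain IDs.
#' @return A `geno_matrix`: list with `map` (the genetic map) and `calls`
#'   (character matrix markers x strains with values "A"/"B"/NA, rownames =
#'   marker IDs, colnames = strain IDs).
#' @examples
#' g <- simulate_segregants(simulate_map(1, 10, 1e5, seed = 1), 20, seed = 2)
#' @export
simulate_segregants <- function(map, n_strains, seed, missing_rate = 0,
                                strain_prefix = "S") {
  map <- .check_map(map)
  stopifnot(n_strains >= 1, missing_rate >= 0, missing_rate < 1)
  set.seed(seed)
  cmkb <- attr(map, "cm_per_kb")
  m <- nrow(map)
  calls <- matrix(NA_character_, m, n_strains)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    r <- haldane(.pos_to_cm(diff(map$pos[idx]), cmkb))
    # allele state as 0/1; cumulative switches modulo 2
    first <- matrix(stats::rbinom(n_strains, 1, 0.5), 1)
    if (length(idx) > 1) {
      sw <- matrix(
        stats::rbinom(length(r) * n_strains, 1, rep(r, n_strains)),
        length(r), n_strains
      )
      state <- (rep(first, each = length(idx)) +
        rbind(0, apply(sw, 2, cumsum))) %% 2
      dim(state) <- c(length(idx), n_strains)
    } else {
      state <- first
    }
    calls[idx, ] <- ifelse(state == 0, "A", "B")
  }
  if (missing_rate > 0) {
    calls[stats::runif(length(calls)) < missing_rate] <- NA_character_
  }
  rownames(calls) <- map$marker
  colnames(calls) <- sprintf(
    paste0(strain_prefix, "%0", nchar(n_strains), "d"), seq_len(n_strains)
  )
  structure(list(map = map, calls = calls), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(
    "Segregant genotypes:", nrow(x$calls), "markers x",
    ncol(x$calls), "strains;",
    sprintf("%.2f%% missing\n", 100 * mean(is.na(x$calls)))
  )
  invisible(x)
}

#' Declare a planted QTL effect
#'
#' Helper building one row block of the QTL effect table consumed by
#' [simulate_phenotypes()]: one additive allele-substitution effect per
#' environment (trait units; the difference between the two genotype-class
#' means). Equal effects across environments define a robust (non-interacting)
#' QTL; unequal effects define a GxE QTL.
#'
#' @param marker Marker ID at which the effect is planted.
#' @param trait Trait name.
#' @param effects Named numeric vector: one effect per environment.
#' @return data.frame with columns `marker`, `trait`, `environment`, `effect`.
#' @export
qtl_effect <- function(marker, trait, effects) {
  stopifnot(length(names(effects)) == length(effects))
  data.frame(
    marker = marker, trait = trait,
    environment = names(effects), effect = as.numeric(effects),
    stringsAsFactors = FALSE
  )
}

#' Default environment labels of the three-condition fermentation design
#'
#' White grape must shaken (`SB14_Sk`), red must shaken (`M15_Sk`) and red
#' must unshaken (`M15`): the SB14_Sk vs M15_Sk contrast probes the grape-must
#' (GM) effect and M15_Sk vs M15 probes micro-oxygenation (shaking).
#' @return Character vector of the three condition labels.
#' @export
default_environments <- function() c("SB14_Sk", "M15_Sk", "M15")

#' Simulate a phenotype table from genotypes and planted QTLs
#'
#' Realises the two-way strain-by-environment structure
#' y = m + S + E + S*E + e, where the strain main effect and the
#' strain-by-environment interaction are driven by the planted QTL effects
#' (each marker contributes `effect * (+1/2 or -1/2)` by genotype class, per
#' environment) plus a polygenic strain deviate constant across environments,
#' and e is replicate noise.
#'
#' @param geno A `geno_matrix`.
#' @param qtls QTL effect table from [qtl_effect()] rows (may be empty/NULL).
#' @param env_means Named numeric vector of per-environment baselines; its
#'   names define the environments.
#' @param strain_sd SD of the polygenic strain deviate (per trait).
#' @param residual_sd SD of the replicate residual.
#' @param n_replicates Replicates per strain x environment (default 2,
#'   matching the duplicate design).
#' @param seed Integer seed.
#' @param traits Trait names to generate; defaults to the traits named in
#'   `qtls`, or `"trait1"` when no QTLs are planted.
#' @return A long-format `data.frame` with columns `strain`, `environment`,
#'   `replicate`, `trait`, `value`.
#' @export
simulate_phenotypes <- function(geno, qtls = NULL, env_means,
                                strain_sd = 1, residual_sd = 0.5,
                                n_replicates = 2, seed,
                                traits = NULL) {
  stopifnot(inherits(geno, "geno_matrix"), n_replicates >= 1,
            strain_sd >= 0, residual_sd >= 0,
            !is.null(names(env_means)))
  envs <- names(env_means)
  if (is.null(traits)) {
    traits <- if (!is.null(qtls) && nrow(qtls)) unique(qtls$trait) else "trait1"
  }
  if (!is.null(qtls) && nrow(qtls)) {
    bad <- setdiff(qtls$marker, rownames(geno$calls))
    if (length(bad)) stop("unknown QTL marker(s): ", paste(bad, collapse = ", "))
    bad_env <- setdiff(qtls$environment, envs)
    if (length(bad_env)) stop("unknown environment(s) in QTL spec: ",
                              paste(bad_env, collapse = ", "))
  }
  set.seed(seed)
  strains <- colnames(geno$calls)
  n <- length(strains)
  out <- vector("list", length(traits))
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    strain_dev <- stats::rnorm(n, 0, strain_sd)
    # genetic value per strain x environment
    gval <- matrix(0, n, length(envs), dimnames = list(strains, envs))
    if (!is.null(qtls) && nrow(qtls)) {
      qt <- qtls[qtls$trait == tr, , drop = FALSE]
      for (i in seq_len(nrow(qt))) {
        x <- ifelse(geno$calls[qt$marker[i], ] == "A", 0.5, -0.5)
        x[is.na(x)] <- 0
        gval[, qt$environment[i]] <- gval[, qt$environment[i]] +
          qt$effect[i] * x
      }
    }
    recs <- expand.grid(
      replicate = seq_len(n_replicates), environment = envs, strain = strains,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    mu <- env_means[recs$environment] +
      strain_dev[match(recs$strain, strains)] +
      gval[cbind(match(recs$strain, strains), match(recs$environment, envs))]
    recs$trait <- tr
    recs$value <- mu + stats::rnorm(nrow(recs), 0, residual_sd)
    out[[ti]] <- recs[, c("strain", "environment", "replicate", "trait", "value")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cumulative CO2 release of a logistic fermentation curve
#'
#' The noiseless generator curve is a logistic sigmoid parameterised by the
#' lag phase (the time at which 2 g/L of CO2 has been released), the maximum
#' release rate (g/L/h, attained at the inflection point) and the plateau
#' (total CO2, g/L):
#' `co2(t) = plateau / (1 + exp(-4 rate (t - t_mid) / plateau))`,
#' with `t_mid` placed so that `co2(lag) = 2`.
#'
#' @param t Times in hours.
#' @param lag Lag phase in hours (time to 2 g/L).
#' @param rate Maximum CO2 release rate (g/L/h).
#' @param plateau Total CO2 released (g/L), > 2.
#' @return CO2 released (g/L) at each time.
#' @export
logistic_co2 <- function(t, lag, rate, plateau) {
  stopifnot(plateau > 2, rate > 0, lag >= 0)
  tmid <- lag + plateau / (4 * rate) * log(plateau / 2 - 1)
  plateau / (1 + exp(-4 * rate * (t - tmid) / plateau))
}

#' Simulate a fermentation CO2 curve
#'
#' Evaluates [logistic_co2()] on a sampling grid and adds independent Gaussian
#' weighing noise, truncated at zero (cumulative CO2 cannot be negative).
#'
#' @param lag,rate,plateau Curve parameters, see [logistic_co2()].
#' @param noise_sd Measurement noise SD in g/L (>= 0).
#' @param times Strictly increasing sampling times (hours), non-empty.
#' @param seed Integer seed (ignored when `noise_sd = 0`).
#' @param sample_id Identifier recorded in the output.
#' @return data.frame with columns `sample_id`, `time_h`, `co2_g_per_l`.
#' @export
simulate_curve <- function(lag, rate, plateau, noise_sd = 0, times, seed = 1,
                           sample_id = "sim") {
  if (length(times) == 0) stop("empty sampling time grid")
  stopifnot(all(diff(times) > 0), noise_sd >= 0)
  co2 <- logistic_co2(times, lag, rate, plateau)
  if (noise_sd > 0) {
    set.seed(seed)
    co2 <- pmax(0, co2 + stats::rnorm(length(times), 0, noise_sd))
  }
  data.frame(
    sample_id = sample_id, time_h = as.numeric(times),
    co2_g_per_l = as.numeric(co2), stringsAsFactors = FALSE
  )
}
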