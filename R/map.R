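#' Haldane map function
#'
#' Converts a genetic distance in centimorgans into a recombination fraction
#' under a no-interference (Poisson) crossover model:
#' r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d_cm Genetic distance in centimorgans (non-negative, vectorised).
#' @return Recombination fraction in [0, 0.5).
#' @examples
#' haldane(c(0, 10, 1e6))
#' @export
haldane <- function(d_cm) {
  stopifnot(is.numeric(d_cm), all(d_cm >= 0))
  (1 - exp(-2 * d_cm / 100)) / 2
}

#' Parse marker identifiers
#'
#' Marker IDs follow the `CHR__CROSS__POS` convention (e.g.
#' `"XVI__SBxGN__371802"`): chromosome label, cross name and 1-based physical
#' position in base pairs, separated by double underscores.
#'
#' @param ids Character vector of marker IDs.
#' @return A data.frame with columns `marker`, `chrom`, `cross`, `pos`.
#' @export
parse_marker_ids <- function(ids) {
  parts <- strsplit(as.character(ids), "__", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed marker id(s): ", paste(ids[bad], collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  if (anyNA(pos)) stop("non-numeric position in marker id(s)")
  data.frame(
    marker = as.character(ids),
    chrom = vapply(parts, `[`, "", 1L),
    cross = vapply(parts, `[`, "", 2L),
    pos = pos,
    stringsAsFactors = FALSE
  )
}

.roman_chrom <- function(i) as.character(utils::as.roman(i))

#' Simulate a marker map
#'
#' Draws marker positions independently and uniformly along each chromosome
#' (without replacement, so positions are strictly increasing) and assigns IDs
#' in the `CHR__CROSS__POS` convention. Physical positions are converted to
#' genetic distances downstream at a fixed rate (`cm_per_kb`), the package-wide
#' default being 0.4 cM/kb, a typical S. cerevisiae genome average.
#'
#' @param n_chromosomes Number of chromosomes (>= 1). Labelled with roman
#'   numerals as in the yeast nomenclature.
#' @param markers_per_chromosome Markers per chromosome (>= 1).
#' @param chromosome_length Chromosome length in base pairs.
#' @param seed Integer seed; the map is deterministic given the seed.
#' @param cross Cross label embedded in marker IDs.
#' @param cm_per_kb Genetic-to-physical rate (centimorgan per kilobase, > 0),
#'   stored as an attribute and used by the recombination model.
#' @return A `genetic_map`: data.frame with columns `marker`, `chrom`, `pos`,
#'   sorted by (chromosome, position), with attribute `cm_per_kb`.
#' @examples
#' m <- simulate_map(2, 5, 1e5, seed = 1)
#' @export
simulate_map <- function(n_chromosomes, markers_per_chromosome,
                         chromosome_length, seed,
                         cross = "SIM", cm_per_kb = 0.4) {
  stopifnot(
    n_chromosomes >= 1, markers_per_chromosome >= 1,
    chromosome_length >= markers_per_chromosome, cm_per_kb > 0
  )
  set.seed(seed)
  maps <- lapply(seq_len(n_chromosomes), function(i) {
    pos <- sort(sample.int(chromosome_length, markers_per_chromosome))
    chrom <- .roman_chrom(i)
    data.frame(
      marker = paste(chrom, cross, pos, sep = "__"),
      chrom = chrom, pos = pos, stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  attr(map, "cm_per_kb") <- cm_per_kb
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(
    "Genetic map:", nrow(x), "markers on",
    length(unique(x$chrom)), "chromosome(s),",
    attr(x, "cm_per_kb"), "cM/kb\n"
  )
  invisible(x)
}

# cM distance between adjacent positions (bp) on the same chromosome
.pos_to_cm <- function(dpos_bp, cm_per_kb) abs(dpos_bp) / 1000 * cm_per_kb

# validate a map-like data.frame, return it with guaranteed sort order
.check_map <- function(map) {
  stopifnot(all(c("marker", "chrom", "pos") %in% names(map)))
  if (is.null(attr(map, "cm_per_kb"))) attr(map, "cm_per_kb") <- 0.4
  o <- order(map$chrom, map$pos)
  if (!identical(o, seq_len(nrow(map)))) {
    map <- map[o, , drop = FALSE]
    rownames(map) <- NULL
  }
  if (anyDuplicated(map$marker)) stop("duplicate marker IDs in map")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions not strictly increasing on ", ch)
  }
  map
}
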