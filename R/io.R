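#' Read a genotype matrix from TSV
#'
#' Expects a header row with `marker` as the first column (IDs in the
#' `CHR__CROSS__POS` convention) and one column per strain; cells are `A`
#' (first parent), `B` (second parent) or empty/`NA` (missing). Heterozygous
#' or otherwise unknown symbols are rejected with the offending cells listed;
#' strains with no calls at all are rejected; markers are sorted by
#' (chromosome, position), with a warning if the file was unsorted.
#'
#' @param path TSV file path.
#' @param cm_per_kb Genetic-to-physical rate attached to the map
#'   (default 0.4 cM/kb).
#' @return A `geno_matrix`.
#' @export
read_genotypes <- function(path, cm_per_kb = 0.4) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("", "NA"))
  if (names(tab)[1] != "marker") stop("first column must be 'marker'")
  if (ncol(tab) < 2) stop("no strain columns")
  ids <- tab$marker
  if (anyDuplicated(ids)) {
    stop("duplicate marker IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  calls <- as.matrix(tab[, -1, drop = FALSE])
  bad <- !(calls %in% c("A", "B") | is.na(calls))
  dim(bad) <- dim(calls)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)
    cells <- sprintf("%s[%s] = '%s'", colnames(calls)[w[, 2]],
                     ids[w[, 1]], calls[bad])
    stop("unknown genotype symbol(s) (homozygous A/B only): ",
         paste(utils::head(cells, 5), collapse = "; "))
  }
  allna <- colSums(!is.na(calls)) == 0
  if (any(allna)) {
    stop("strain(s) with no genotype calls: ",
         paste(colnames(calls)[allna], collapse = ", "))
  }
  pm <- parse_marker_ids(ids)
  map <- data.frame(marker = ids, chrom = pm$chrom, pos = pm$pos,
                    stringsAsFactors = FALSE)
  o <- order(map$chrom, map$pos)
  if (!identical(o, seq_along(ids))) {
    warning("markers were not sorted by (chromosome, position); sorting")
    map <- map[o, , drop = FALSE]
    calls <- calls[o, , drop = FALSE]
  }
  rownames(map) <- NULL
  rownames(calls) <- map$marker
  attr(map, "cm_per_kb") <- cm_per_kb
  class(map) <- c("genetic_map", "data.frame")
  structure(list(map = map, calls = calls), class = "geno_matrix")
}

#' Write a genotype matrix to TSV
#'
#' @param geno A `geno_matrix`.
#' @param path Output path. Missing calls are written as empty cells.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "geno_matrix"))
  out <- data.frame(marker = rownames(geno$calls), geno$calls,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a phenotype table from TSV
#'
#' Accepts the long layout (`strain, environment, replicate, trait, value`)
#' or a wide layout (`strain, environment, replicate` plus one numeric column
#' per trait), which is melted to long form. Duplicate
#' (strain, environment, replicate, trait) keys and non-numeric value cells
#' are rejected with the offending rows reported.
#'
#' @param path TSV file path.
#' @return Long-format data.frame `strain, environment, replicate, trait,
#'   value`.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("", "NA"),
                           colClasses = "character")
  need <- c("strain", "environment", "replicate")
  if (!all(need %in% names(tab))) {
    stop("missing required column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (all(c("trait", "value") %in% names(tab))) {
    long <- tab[, c(need, "trait", "value")]
  } else {
    traits <- setdiff(names(tab), need)
    if (!length(traits)) stop("no trait columns")
    long <- do.call(rbind, lapply(traits, function(tr) {
      data.frame(tab[, need], trait = tr, value = tab[[tr]],
                 stringsAsFactors = FALSE)
    }))
  }
  num <- suppressWarnings(as.numeric(long$value))
  bad <- !is.na(long$value) & is.na(num)
  if (any(bad)) {
    stop("non-numeric value(s) at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  long$value <- num
  long$replicate <- as.integer(long$replicate)
  key <- paste(long$strain, long$environment, long$replicate, long$trait,
               sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (strain, environment, replicate, trait) record(s), e.g. ",
         gsub("\r", "/", key[duplicated(key)][1]))
  }
  rownames(long) <- NULL
  long
}

#' Write a phenotype table to TSV (long layout)
#'
#' @param pheno Long phenotype table.
#' @param path Output path. Missing values are written as empty cells.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(
    pheno[, c("strain", "environment", "replicate", "trait", "value")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = ""
  )
  invisible(path)
}

#' Read fermentation curves from TSV
#'
#' Columns `sample_id`, `time_h`, `co2_g_per_l`; one block per fermentation.
#' @param path TSV file path.
#' @return data.frame of stacked curves.
#' @export
read_curves <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_h", "co2_g_per_l")
  if (!all(need %in% names(tab))) {
    stop("missing required column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  tab$time_h <- as.numeric(tab$time_h)
  tab$co2_g_per_l <- as.numeric(tab$co2_g_per_l)
  tab[, need]
}

#' Write fermentation curves to TSV
#' @param curves data.frame `sample_id, time_h, co2_g_per_l`.
#' @param path Output path.
#' @export
write_curves <- function(curves, path) {
  utils::write.table(curves[, c("sample_id", "time_h", "co2_g_per_l")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a kinetic trait table to TSV
#' @param traits [fit_kinetics()] output (or any data.frame with
#'   `sample_id` and trait columns). Undefined traits become empty cells.
#' @param path Output path.
#' @export
write_kinetics <- function(traits, path) {
  utils::write.table(as.data.frame(traits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a scan result to TSV
#' @param scan A `qtl_scan`.
#' @param path Output path.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "qtl_scan"))
  out <- cbind(trait = scan$trait, scan$result)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a labeled square distance matrix to TSV
#' @param D Symmetric matrix with row/col labels.
#' @param path Output path.
#' @export
write_distance_matrix <- function(D, path) {
  out <- data.frame(strain = rownames(D), D, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled square distance matrix from TSV
#' @param path TSV written by [write_distance_matrix()].
#' @return Symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}
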