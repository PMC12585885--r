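#' Genotype matrix container
#'
#' The central data structure of the package: an individuals-by-sites matrix
#' of alternate-allele dosages (0, 1, 2 or `NA` for missing) together with a
#' site table giving chromosome, 1-based position and the two alleles of each
#' biallelic SNP.
#'
#' @param dosage integer matrix, samples in rows, sites in columns; values in
#'   `{0, 1, 2, NA}`.
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt`. A `site_id` column is added if absent.
#' @param samples character vector of unique sample ids, one per row of
#'   `dosage`.
#' @return An object of class `genotype_matrix` with elements `samples`,
#'   `sites` and `dosage`.
#' @export
genotype_matrix <- function(dosage, sites, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  samples <- as.character(samples)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (is.null(sites$site_id)) sites$site_id <- seq_len(nrow(sites))
  stopifnot(
    nrow(dosage) == length(samples),
    ncol(dosage) == nrow(sites),
    all(c("chrom", "pos", "ref", "alt") %in% names(sites))
  )
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad, na.rm = TRUE)) stop("dosage values must be 0, 1, 2 or NA")
  # positions strictly increasing within each chromosome
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0)) {
      stop("site positions must be strictly increasing within chromosome ", ch)
    }
  }
  rownames(dosage) <- samples
  structure(
    list(samples = samples, sites = sites, dosage = dosage),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x", nrow(x$sites),
      "sites on", length(unique(x$sites$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids (or logical/integer index) to keep; `NULL` keeps
#'   all.
#' @param sites logical or integer index over sites to keep; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the requested samples and sites.
#' @export
gm_subset <- function(gm, samples = NULL, sites = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ri <- seq_along(gm$samples)
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, gm$samples) else ri[samples]
    if (anyNA(ri)) stop("unknown sample id(s)")
  }
  ci <- seq_len(nrow(gm$sites))
  if (!is.null(sites)) ci <- ci[sites]
  genotype_matrix(gm$dosage[ri, ci, drop = FALSE],
                  gm$sites[ci, , drop = FALSE],
                  gm$samples[ri])
}

#' Restrict a genotype matrix to a genomic region
#'
#' @param gm a [genotype_matrix()].
#' @param chrom chromosome id.
#' @param start,end 0-based half-open interval in bp; defaults cover the
#'   whole chromosome.
#' @export
gm_region <- function(gm, chrom, start = 0L, end = Inf) {
  keep <- gm$sites$chrom == chrom & gm$sites$pos > start & gm$sites$pos <= end
  gm_subset(gm, sites = keep)
}

#' Per-site alternate allele frequencies
#'
#' Frequencies are computed over non-missing calls only.
#'
#' @param gm a [genotype_matrix()].
#' @param samples optional subset of sample ids.
#' @return Numeric vector of alt-allele frequencies, `NaN` where all calls
#'   are missing.
#' @export
allele_freq <- function(gm, samples = NULL) {
  d <- if (is.null(samples)) gm$dosage else
    gm$dosage[match(samples, gm$samples), , drop = FALSE]
  n <- 2L * colSums(!is.na(d))
  colSums(d, na.rm = TRUE) / n
}

# internal: dosage rows for a set of sample ids, with checks
.gm_rows <- function(gm, samples) {
  i <- match(samples, gm$samples)
  if (anyNA(i)) stop("unknown sample id(s): ",
                     paste(samples[is.na(i)], collapse = ", "))
  gm$dosage[i, , drop = FALSE]
}
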