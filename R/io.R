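#' Read a SNP VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (plain or gzipped) with vcfR, keeping biallelic SNP
#' records only. Multiallelic or non-SNP records are skipped and their count
#' reported via `message()`. Dosages are decoded from the GT field regardless
#' of phasing; any GT containing `.` is treated as missing.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @param region optional `list(chrom=, start=, end=)` (0-based half-open) to
#'   restrict the returned sites.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) stop("VCF contains no samples: ", path)
  ref <- fix$REF
  alt <- fix$ALT
  is_snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    !grepl(",", alt, fixed = TRUE)
  n_skip <- sum(!is_snp)
  if (n_skip > 0) {
    message("read_vcf: skipped ", n_skip, " multiallelic/non-SNP record(s)")
  }
  if (!any(is_snp)) stop("no biallelic SNP records in ", path)
  fix <- fix[is_snp, , drop = FALSE]
  gt <- gt[is_snp, , drop = FALSE]
  samples <- colnames(gt)[-1]
  gtf <- sub(":.*", "", gt[, -1, drop = FALSE])  # GT is first subfield
  gtf[is.na(gtf)] <- "./."
  a1 <- substr(gtf, 1, 1)
  a2 <- substr(gtf, 3, 3)
  dos <- matrix(NA_integer_, nrow = nrow(fix), ncol = length(samples))
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  bad_tok <- !ok & !(a1 == "." | a2 == "." | gtf == ".")
  if (any(bad_tok)) {
    stop("malformed GT field in VCF record line (variant ",
         which(rowSums(matrix(bad_tok, nrow = nrow(fix))) > 0)[1], ")")
  }
  dos[ok] <- (a1[ok] == "1") + (a2[ok] == "1")
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  gm <- genotype_matrix(t(dos[ord, , drop = FALSE]), sites[ord, ], samples)
  if (!is.null(region)) {
    gm <- gm_region(gm, region$chrom, region$start %||% 0L,
                    region$end %||% Inf)
  }
  gm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a genotype matrix as a VCF 4.2 file
#'
#' Output contains GT fields only (`0/0`, `0/1`, `1/1`, `./.`). A `.gz`
#' suffix selects gzip compression; plain output is byte-reproducible.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path, ending in `.vcf` or `.vcf.gz`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_codes <- c("0/0", "0/1", "1/1")
  g <- gm$dosage
  gtxt <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
  ok <- !is.na(g)
  gtxt[ok] <- gt_codes[g[ok] + 1L]
  s <- gm$sites
  rows <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "GT",
                sep = "\t")
  body <- paste0(rows, "\t", apply(gtxt, 2, paste, collapse = "\t"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated file with header `sample_id habitat location dataset`.
#' Habitat must be one of `coastal`, `marine`, `unknown`.
#'
#' @param path TSV path.
#' @param gm optional [genotype_matrix()]; when given, every sample of `gm`
#'   must be present in the sheet.
#' @return data.frame with columns `sample_id`, `habitat`, `location`,
#'   `dataset`.
#' @export
read_sample_sheet <- function(path, gm = NULL) {
  ss <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "habitat", "location", "dataset")
  if (!all(need %in% names(ss))) {
    stop("sample sheet must have columns: ", paste(need, collapse = " "))
  }
  if (anyDuplicated(ss$sample_id)) stop("duplicate sample_id in sheet")
  bad <- setdiff(unique(ss$habitat), c("coastal", "marine", "unknown"))
  if (length(bad)) stop("unknown habitat value(s): ", paste(bad, collapse = ", "))
  if (!is.null(gm)) {
    miss <- setdiff(gm$samples, ss$sample_id)
    if (length(miss)) stop("samples missing from sheet: ",
                           paste(utils::head(miss, 5), collapse = ", "))
  }
  ss
}

#' @rdname read_sample_sheet
#' @param sheet a sample-sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter sites on minor allele frequency
#'
#' Retains sites whose minor-allele frequency, computed over non-missing
#' calls, is strictly greater than `min_maf` (so `min_maf = 0.05` removes a
#' site at exactly 0.05, and `min_maf = 0` removes monomorphic sites only).
#'
#' @param gm a [genotype_matrix()].
#' @param min_maf threshold in `[0, 0.5)`.
#' @export
filter_maf <- function(gm, min_maf = 0.05) {
  stopifnot(min_maf >= 0, min_maf < 0.5)
  p <- allele_freq(gm)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > min_maf
  gm_subset(gm, sites = keep)
}

#' Restrict two genotype matrices to their shared sites
#'
#' Sites match on (chrom, pos, ref, alt); both outputs carry the shared sites
#' in the same order (the order of `gm_a`).
#'
#' @param gm_a,gm_b [genotype_matrix()] objects with the same coordinate
#'   convention.
#' @return List of the two restricted matrices.
#' @export
intersect_sites <- function(gm_a, gm_b) {
  key <- function(g) paste(g$sites$chrom, g$sites$pos, g$sites$ref,
                           g$sites$alt, sep = ":")
  ka <- key(gm_a); kb <- key(gm_b)
  shared <- ka[ka %in% kb]
  if (length(shared) == 0) stop("no shared sites between the two matrices")
  list(a = gm_subset(gm_a, sites = match(shared, ka)),
       b = gm_subset(gm_b, sites = match(shared, kb)))
}

#' Merge samples of two matrices defined on identical sites
#'
#' Duplicate sample ids are resolved by keeping the genotypes of `gm_a`
#' (reported via `message()`).
#'
#' @param gm_a,gm_b matrices with identical site tables (use
#'   [intersect_sites()] first).
#' @export
merge_samples <- function(gm_a, gm_b) {
  sa <- gm_a$sites; sb <- gm_b$sites
  if (nrow(sa) != nrow(sb) ||
      !all(sa$chrom == sb$chrom & sa$pos == sb$pos &
           sa$ref == sb$ref & sa$alt == sb$alt)) {
    stop("site tables differ; run intersect_sites() first")
  }
  dup <- intersect(gm_a$samples, gm_b$samples)
  if (length(dup)) {
    message("merge_samples: ", length(dup),
            " duplicate sample id(s) resolved in favour of the first matrix")
  }
  keep_b <- !(gm_b$samples %in% dup)
  genotype_matrix(rbind(gm_a$dosage, gm_b$dosage[keep_b, , drop = FALSE]),
                  sa, c(gm_a$samples, gm_b$samples[keep_b]))
}
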