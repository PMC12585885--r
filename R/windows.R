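#' Tile chromosomes into non-overlapping windows
#'
#' Windows are 0-based half-open bp intervals (BED convention); a site at
#' 1-based position `pos` falls in window `[a, b)` when `a < pos <= b`.
#' Windows with fewer than `min_sites` usable sites are retained but marked
#' unusable; a trailing window shorter than `size` is marked partial.
#'
#' @param sites site table (`chrom`, `pos`) or a [genotype_matrix()].
#' @param size window size in bp.
#' @param min_sites minimum usable site count.
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the last site position per chromosome.
#' @return data.frame `chrom, start, end, n_sites, usable, partial`.
#' @export
make_windows <- function(sites, size = 5000, min_sites = 15,
                         chrom_lengths = NULL) {
  if (inherits(sites, "genotype_matrix")) sites <- sites$sites
  out <- list()
  for (ch in unique(sites$chrom)) {
    pos <- sites$pos[sites$chrom == ch]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else max(pos)
    starts <- seq(0L, len - 1L, by = size)
    ends <- pmin(starts + size, len)
    counts <- as.integer(table(factor(
      findInterval(pos - 1L, starts), levels = seq_along(starts))))
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            n_sites = counts,
                            usable = counts >= min_sites,
                            partial = ends - starts < size,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# internal: per-site allele summaries for one population
.site_freq <- function(gm, samples) {
  d <- .gm_rows(gm, samples)
  nd <- colSums(!is.na(d))          # diploids with calls
  n <- 2 * nd                       # allele count
  p <- colSums(d, na.rm = TRUE) / n
  het <- colSums(d == 1L, na.rm = TRUE) / nd
  list(p = p, n = n, nd = nd, het = het)
}

# internal: map sites to row indices of a window table (NA if outside)
.site_window <- function(gm, windows) {
  idx <- rep(NA_integer_, nrow(gm$sites))
  for (ch in unique(windows$chrom)) {
    w <- which(windows$chrom == ch)
    s <- which(gm$sites$chrom == ch)
    k <- findInterval(gm$sites$pos[s] - 1L, windows$start[w])
    k[k < 1 | (gm$sites$pos[s] - 1L) >= windows$end[w][pmax(k, 1)]] <- NA
    idx[s] <- w[k]
  }
  idx
}

#' Nucleotide diversity in a window
#'
#' Per-bp diversity: sum over sites of `2 p (1-p) n/(n-1)` (allele counts
#' over non-missing calls), divided by the window's bp span. Equals the mean
#' pairwise per-bp difference between allele copies.
#'
#' @param gm a [genotype_matrix()].
#' @param pop_samples sample ids of the population.
#' @param window `list(chrom=, start=, end=)`, 0-based half-open.
#' @export
pi_window <- function(gm, pop_samples, window) {
  g <- gm_region(gm, window$chrom, window$start, window$end)
  if (nrow(g$sites) == 0) return(0)
  f <- .site_freq(g, pop_samples)
  ok <- f$n >= 2
  sum(2 * f$p[ok] * (1 - f$p[ok]) * f$n[ok] / (f$n[ok] - 1)) /
    (window$end - window$start)
}

#' Absolute divergence d_XY in a window
#'
#' Per-bp divergence: sum over sites of `pA(1-pB) + pB(1-pA)` divided by the
#' window's bp span.
#'
#' @inheritParams pi_window
#' @param popA,popB sample id vectors for the two populations.
#' @export
dxy_window <- function(gm, popA, popB, window) {
  g <- gm_region(gm, window$chrom, window$start, window$end)
  if (nrow(g$sites) == 0) return(0)
  fa <- .site_freq(g, popA); fb <- .site_freq(g, popB)
  ok <- fa$n >= 1 & fb$n >= 1
  sum(fa$p[ok] * (1 - fb$p[ok]) + fb$p[ok] * (1 - fa$p[ok])) /
    (window$end - window$start)
}

# internal: per-site Hudson numerator/denominator (Bhatia et al. estimator)
.hudson_site <- function(fa, fb) {
  valid <- fa$nd >= 2 & fb$nd >= 2
  num <- (fa$p - fb$p)^2 -
    fa$p * (1 - fa$p) / (fa$n - 1) - fb$p * (1 - fb$p) / (fb$n - 1)
  den <- fa$p * (1 - fb$p) + fb$p * (1 - fa$p)
  num[!valid] <- NA; den[!valid] <- NA
  list(num = num, den = den, valid = valid)
}

# internal: per-site Weir-Cockerham variance components (two populations)
.wc_site <- function(fa, fb) {
  valid <- fa$nd >= 2 & fb$nd >= 2
  n1 <- fa$nd; n2 <- fb$nd
  p1 <- fa$p; p2 <- fb$p
  h1 <- fa$het; h2 <- fb$het
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!valid] <- NA; b[!valid] <- NA; cc[!valid] <- NA
  list(a = a, b = b, c = cc, valid = valid)
}

#' F_ST in a window
#'
#' Hudson (default): ratio of averages of the Bhatia et al. per-site
#' numerator (`(pA-pB)^2` minus sampling corrections) over the between-pop
#' heterozygosity `pA qB + pB qA`. Weir-Cockerham: ratio of summed variance
#' components. Sites with fewer than 2 non-missing diploids in either
#' population are excluded; a window with no valid site yields `NA`.
#'
#' @inheritParams dxy_window
#' @param method `"hudson"` or `"wc"`.
#' @export
fst_window <- function(gm, popA, popB, window, method = c("hudson", "wc")) {
  method <- match.arg(method)
  g <- gm_region(gm, window$chrom, window$start, window$end)
  if (nrow(g$sites) == 0) return(NA_real_)
  fa <- .site_freq(g, popA); fb <- .site_freq(g, popB)
  if (method == "hudson") {
    h <- .hudson_site(fa, fb)
    if (!any(h$valid)) return(NA_real_)
    sum(h$num, na.rm = TRUE) / sum(h$den, na.rm = TRUE)
  } else {
    w <- .wc_site(fa, fb)
    if (!any(w$valid)) return(NA_real_)
    sum(w$a, na.rm = TRUE) /
      sum(w$a + w$b + w$c, na.rm = TRUE)
  }
}

#' Windowed differentiation and diversity table
#'
#' Computes pi for both populations, d_XY and F_ST in every window in one
#' vectorized pass. Unusable windows (below the `min_sites` rule encoded in
#' `windows$usable`) carry `NA` statistics.
#'
#' @param gm a [genotype_matrix()].
#' @param popA,popB sample id vectors.
#' @param windows window table from [make_windows()].
#' @param method F_ST estimator, `"hudson"` or `"wc"`.
#' @return `windows` with columns `pi_A, pi_B, dxy, fst` added and
#'   `flag = "none"` (see [quantile_flags()]).
#' @export
window_stats <- function(gm, popA, popB, windows,
                         method = c("hudson", "wc")) {
  method <- match.arg(method)
  fa <- .site_freq(gm, popA)
  fb <- .site_freq(gm, popB)
  widx <- .site_window(gm, windows)
  span <- windows$end - windows$start
  acc <- function(x, ok) {
    keep <- !is.na(widx) & ok & !is.na(x)
    out <- numeric(nrow(windows))
    if (!any(keep)) return(out)
    v <- rowsum(x[keep], widx[keep])
    out[as.integer(rownames(v))] <- v
    out
  }
  pi_term <- function(f) 2 * f$p * (1 - f$p) * f$n / (f$n - 1)
  pi_A <- acc(pi_term(fa), fa$n >= 2) / span
  pi_B <- acc(pi_term(fb), fb$n >= 2) / span
  dxy <- acc(fa$p * (1 - fb$p) + fb$p * (1 - fa$p),
             fa$n >= 1 & fb$n >= 1) / span
  if (method == "hudson") {
    h <- .hudson_site(fa, fb)
    fst <- acc(h$num, h$valid) / acc(h$den, h$valid)
  } else {
    w <- .wc_site(fa, fb)
    fst <- acc(w$a, w$valid) / acc(w$a + w$b + w$c, w$valid)
  }
  nvalid <- acc(rep(1, length(widx)), if (method == "hudson")
    .hudson_site(fa, fb)$valid else .wc_site(fa, fb)$valid)
  fst[nvalid == 0] <- NA
  out <- windows
  out$pi_A <- ifelse(out$usable, pi_A, NA)
  out$pi_B <- ifelse(out$usable, pi_B, NA)
  out$dxy <- ifelse(out$usable, dxy, NA)
  out$fst <- ifelse(out$usable, fst, NA)
  out$flag <- "none"
  out
}

#' Per-individual heterozygosity
#'
#' Fraction of heterozygous calls among non-missing calls per sample, over a
#' region or the whole matrix.
#'
#' @param gm a [genotype_matrix()].
#' @param region optional `list(chrom=, start=, end=)`.
#' @return Named numeric vector, one value per sample.
#' @export
individual_het <- function(gm, region = NULL) {
  if (!is.null(region)) {
    gm <- gm_region(gm, region$chrom, region$start %||% 0L,
                    region$end %||% Inf)
  }
  d <- gm$dosage
  rowSums(d == 1L, na.rm = TRUE) / rowSums(!is.na(d))
}

#' Squared genotype correlation between two sites
#'
#' Squared Pearson correlation of the dosage vectors over pairwise-complete
#' samples.
#'
#' @param gm a [genotype_matrix()].
#' @param site_i,site_j site indices (columns of the dosage matrix).
#' @export
geno_r2 <- function(gm, site_i, site_j) {
  suppressWarnings(
    stats::cor(gm$dosage[, site_i], gm$dosage[, site_j],
               use = "pairwise.complete.obs")^2)
}

#' Mean r-squared in windows of consecutive SNPs
#'
#' @param gm a [genotype_matrix()].
#' @param chrom chromosome id.
#' @param n_snps SNPs per LD window.
#' @param samples optional sample subset.
#' @return data.frame `chrom, start_pos, end_pos, n_pairs, mean_r2`.
#' @export
ld_window_r2 <- function(gm, chrom, n_snps = 50, samples = NULL) {
  g <- gm_region(gm, chrom)
  if (!is.null(samples)) g <- gm_subset(g, samples = samples)
  L <- nrow(g$sites)
  starts <- seq(1L, L, by = n_snps)
  out <- lapply(starts, function(s) {
    e <- min(s + n_snps - 1L, L)
    if (e - s < 1) return(NULL)
    d <- g$dosage[, s:e, drop = FALSE]
    suppressWarnings(r <- stats::cor(d, use = "pairwise.complete.obs")^2)
    up <- r[upper.tri(r)]
    data.frame(chrom = chrom, start_pos = g$sites$pos[s],
               end_pos = g$sites$pos[e], n_pairs = sum(!is.na(up)),
               mean_r2 = mean(up, na.rm = TRUE))
  })
  do.call(rbind, out)
}

#' Flag windows above genome-wide F_ST quantiles
#'
#' Thresholds are the genome-wide empirical quantiles (linear interpolation,
#' type 7) of window F_ST over usable windows; a window is flagged `q95`
#' (`q99`) when its F_ST is strictly above the 95th (99th) quantile. Windows
#' above the 99th quantile are a subset of those above the 95th and carry
#' the `q99` label.
#'
#' @param stat_table output of [window_stats()].
#' @param probs the two quantile levels.
#' @param comparator `">"` (strict, default, matching the "higher than"
#'   wording) or `">="`.
#' @return `stat_table` with its `flag` column filled.
#' @export
quantile_flags <- function(stat_table, probs = c(0.95, 0.99),
                           comparator = c(">", ">=")) {
  comparator <- match.arg(comparator)
  cmp <- match.fun(comparator)
  x <- stat_table$fst
  ok <- stat_table$usable & !is.na(x)
  th <- stats::quantile(x[ok], probs, type = 7, names = FALSE)
  flag <- rep("none", nrow(stat_table))
  flag[ok & cmp(x, th[1])] <- "q95"
  flag[ok & cmp(x, th[2])] <- "q99"
  stat_table$flag <- flag
  attr(stat_table, "thresholds") <- stats::setNames(th, c("q95", "q99"))
  stat_table
}

#' Flag chromosomes as SV candidates
#'
#' A chromosome is flagged when the fraction of its usable windows carrying a
#' `q95` flag (including `q99`) exceeds `threshold` (default 0.025, strict
#' comparison).
#'
#' @param stat_table a flagged table from [quantile_flags()].
#' @param threshold fraction of flagged windows required.
#' @param comparator `">"` (strict, default) or `">="`.
#' @return data.frame `chrom, n_usable, n_flagged, frac, sv_flag`.
#' @export
chromosome_sv_flag <- function(stat_table, threshold = 0.025,
                               comparator = c(">", ">=")) {
  comparator <- match.arg(comparator)
  cmp <- match.fun(comparator)
  use <- stat_table[stat_table$usable & !is.na(stat_table$fst), ]
  agg <- lapply(split(use, use$chrom), function(d) {
    nf <- sum(d$flag %in% c("q95", "q99"))
    data.frame(chrom = d$chrom[1], n_usable = nrow(d), n_flagged = nf,
               frac = nf / nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  out$sv_flag <- cmp(out$frac, threshold)
  out[order(out$chrom), , drop = FALSE]
}
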