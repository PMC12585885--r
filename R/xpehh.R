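#' Unphased EHH decay curve around a core site
#'
#' Multilocus-genotype EHH: at extension distance d, individuals are grouped
#' by the identity of their genotype vector over the sites strictly beyond
#' the core out to d, and
#' `EHH(d) = sum_g n_g (n_g - 1) / (n (n - 1))`. By this identity-class
#' definition EHH(0) = 1, and the curve is non-increasing. The curve is
#' truncated when EHH drops below `cutoff`, when an inter-site gap exceeds
#' `max_gap`, or at the last site.
#'
#' Individuals with a missing genotype at an extension site are dropped from
#' that distance onward; the curve ends when fewer than 2 remain.
#'
#' @param gm a [genotype_matrix()].
#' @param pop sample ids of the population.
#' @param core_site site index (column of the dosage matrix).
#' @param direction `"left"` or `"right"` along the chromosome.
#' @param cutoff EHH truncation level.
#' @param max_gap maximum bp between consecutive sites before truncation.
#' @return data.frame `distance` (bp from core), `ehh`; first row is
#'   `(0, 1)`.
#' @export
ehh_unphased <- function(gm, pop, core_site, direction = c("right", "left"),
                         cutoff = 0.05, max_gap = 200000) {
  direction <- match.arg(direction)
  d <- .gm_rows(gm, pop)
  ch <- gm$sites$chrom[core_site]
  core_pos <- gm$sites$pos[core_site]
  on_chrom <- which(gm$sites$chrom == ch)
  idx <- if (direction == "right") {
    on_chrom[gm$sites$pos[on_chrom] > core_pos]
  } else {
    rev(on_chrom[gm$sites$pos[on_chrom] < core_pos])
  }
  alive <- seq_len(nrow(d))
  n0 <- length(alive)                  # fixed denominator keeps EHH monotone
  if (n0 < 2) stop("fewer than 2 individuals")
  dist <- 0
  ehh <- 1
  grp <- rep(1L, nrow(d))
  last_pos <- core_pos
  for (s in idx) {
    pos <- gm$sites$pos[s]
    if (abs(pos - last_pos) > max_gap) break
    g <- d[, s]
    alive <- alive[!is.na(g[alive])]   # missing drops to a dead singleton
    if (length(alive) < 2) break
    grp[alive] <- as.integer(interaction(grp[alive], g[alive], drop = TRUE))
    cnt <- tabulate(grp[alive])
    e <- sum(cnt * (cnt - 1)) / (n0 * (n0 - 1))
    dist <- c(dist, abs(pos - core_pos))
    ehh <- c(ehh, e)
    last_pos <- pos
    if (e < cutoff) break
  }
  data.frame(distance = dist, ehh = ehh)
}

#' Integrated EHH (iHH)
#'
#' Trapezoidal integral of the EHH curves over physical distance, both
#' directions summed. Integration stops at the cutoff crossing, linearly
#' interpolated to the crossing point; a curve that never crosses is
#' integrated to its end.
#'
#' @param curve_left,curve_right data.frames from [ehh_unphased()].
#' @param cutoff EHH level where integration stops.
#' @return The summed area (bp).
#' @export
ihh <- function(curve_left, curve_right, cutoff = 0.05) {
  one <- function(cv) {
    if (is.null(cv) || nrow(cv) < 2) return(0)
    x <- cv$distance; y <- cv$ehh
    area <- 0
    for (i in seq_len(nrow(cv) - 1)) {
      if (y[i + 1] >= cutoff) {
        area <- area + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
      } else {
        # interpolate to the crossing point and stop
        xc <- x[i] + (x[i + 1] - x[i]) * (y[i] - cutoff) / (y[i] - y[i + 1])
        area <- area + (xc - x[i]) * (y[i] + cutoff) / 2
        break
      }
    }
    area
  }
  one(curve_left) + one(curve_right)
}

#' Cross-population XP-EHH scan on unphased genotypes
#'
#' Per core site, `ln(iHH_A / iHH_B)` from the unphased genotype-identity
#' EHH of each population, genome-standardized to z-scores (single bin:
#' the unphased statistic has no derived-allele frequency conditioning).
#' Cores where either iHH is zero or undefined are dropped.
#'
#' @param gm a [genotype_matrix()].
#' @param popA,popB sample id vectors.
#' @param cores site indices to scan; default all sites polymorphic in the
#'   joint sample.
#' @param cutoff EHH cutoff for curve truncation and integration.
#' @param max_gap see [ehh_unphased()].
#' @return data.frame `site_id, chrom, pos, ihh_a, ihh_b, ln_ratio, z` of
#'   class `xpehh_scan`.
#' @export
xpehh_scan <- function(gm, popA, popB, cores = NULL, cutoff = 0.05,
                       max_gap = 200000) {
  if (is.null(cores)) {
    p <- allele_freq(gm, c(popA, popB))
    cores <- which(!is.na(p) & p > 0 & p < 1)
  }
  rows <- lapply(cores, function(s) {
    ia <- ihh(ehh_unphased(gm, popA, s, "left", cutoff, max_gap),
              ehh_unphased(gm, popA, s, "right", cutoff, max_gap), cutoff)
    ib <- ihh(ehh_unphased(gm, popB, s, "left", cutoff, max_gap),
              ehh_unphased(gm, popB, s, "right", cutoff, max_gap), cutoff)
    data.frame(site_id = s, chrom = gm$sites$chrom[s], pos = gm$sites$pos[s],
               ihh_a = ia, ihh_b = ib, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- out$ihh_a > 0 & out$ihh_b > 0
  if (any(!ok)) {
    message("xpehh_scan: dropped ", sum(!ok),
            " core(s) with zero/undefined iHH")
  }
  out <- out[ok, , drop = FALSE]
  out$ln_ratio <- log(out$ihh_a) - log(out$ihh_b)  # exact under pop swap
  sd0 <- stats::sd(out$ln_ratio)
  out$z <- if (isTRUE(sd0 > 0)) {
    (out$ln_ratio - mean(out$ln_ratio)) / sd0
  } else {
    rep(0, nrow(out))
  }
  class(out) <- c("xpehh_scan", "data.frame")
  out
}
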