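# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately use naive loops over pairs of allele
# copies / sites, not the package's code paths.

# genotype matrix from a plain dosage matrix (rows = samples)
make_gm <- function(dos, chrom = "chr01", pos = NULL, samples = NULL) {
  dos <- as.matrix(dos)
  if (is.null(pos)) pos <- seq_len(ncol(dos)) * 10L
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(dos)))
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_matrix(dos, sites, samples)
}

# expand a dosage column into allele copies (0/1), dropping missing
.alleles <- function(g) {
  g <- g[!is.na(g)]
  unlist(lapply(g, function(d) c(rep(1, d), rep(0, 2 - d))))
}

# pi as the mean pairwise difference over all allele-copy pairs
oracle_pi <- function(dos, span) {
  tot <- 0
  for (j in seq_len(ncol(dos))) {
    a <- .alleles(dos[, j])
    n <- length(a)
    if (n < 2) next
    diffs <- 0
    for (x in seq_len(n - 1)) for (y in (x + 1):n) {
      diffs <- diffs + (a[x] != a[y])
    }
    tot <- tot + diffs / choose(n, 2)
  }
  tot / span
}

# d_XY as the mean difference over all between-population allele pairs
oracle_dxy <- function(dosA, dosB, span) {
  tot <- 0
  for (j in seq_len(ncol(dosA))) {
    a <- .alleles(dosA[, j]); b <- .alleles(dosB[, j])
    if (length(a) < 1 || length(b) < 1) next
    diffs <- 0
    for (x in seq_along(a)) for (y in seq_along(b)) {
      diffs <- diffs + (a[x] != b[y])
    }
    tot <- tot + diffs / (length(a) * length(b))
  }
  tot / span
}

# Hudson F_ST: per-site Bhatia numerator / between-pop heterozygosity,
# ratio of averages, written site-by-site
oracle_hudson <- function(dosA, dosB) {
  num <- den <- c()
  for (j in seq_len(ncol(dosA))) {
    ga <- dosA[, j][!is.na(dosA[, j])]; gb <- dosB[, j][!is.na(dosB[, j])]
    if (length(ga) < 2 || length(gb) < 2) next
    na <- 2 * length(ga); nb <- 2 * length(gb)
    pa <- sum(ga) / na; pb <- sum(gb) / nb
    num <- c(num, (pa - pb)^2 - pa * (1 - pa) / (na - 1) -
               pb * (1 - pb) / (nb - 1))
    den <- c(den, pa * (1 - pb) + pb * (1 - pa))
  }
  sum(num) / sum(den)
}

# EHH by exhaustive pair counting of multilocus genotype identity
# (sites strictly beyond the core, core excluded; fixed denominator)
oracle_ehh <- function(dos, pos, core_idx, direction) {
  n <- nrow(dos)
  ord <- if (direction == "right") {
    which(pos > pos[core_idx])[order(pos[pos > pos[core_idx]])]
  } else {
    rev(which(pos < pos[core_idx])[order(pos[pos < pos[core_idx]])])
  }
  out <- data.frame(distance = 0, ehh = 1)
  for (m in seq_along(ord)) {
    span_sites <- ord[seq_len(m)]
    pairs <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      gi <- dos[i, span_sites]; gj <- dos[j, span_sites]
      if (!anyNA(gi) && !anyNA(gj) && all(gi == gj)) pairs <- pairs + 1
    }
    e <- 2 * pairs / (n * (n - 1))
    out <- rbind(out, data.frame(distance = abs(pos[ord[m]] - pos[core_idx]),
                                 ehh = e))
    if (e < 0.05) break
  }
  out
}

# trapezoid integration with cutoff interpolation, written independently
oracle_ihh_one <- function(distance, ehh, cutoff = 0.05) {
  area <- 0
  for (i in seq_along(distance)[-1]) {
    x0 <- distance[i - 1]; x1 <- distance[i]
    y0 <- ehh[i - 1]; y1 <- ehh[i]
    if (y1 >= cutoff) {
      area <- area + (x1 - x0) * (y0 + y1) / 2
    } else {
      xc <- x0 + (x1 - x0) * (y0 - cutoff) / (y0 - y1)
      area <- area + (xc - x0) * (y0 + cutoff) / 2
      break
    }
  }
  area
}

# allele-sharing distance, per-pair loop
oracle_diff_matrix <- function(dos) {
  n <- nrow(dos)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(dos[i, ]) & !is.na(dos[j, ])
    D[i, j] <- D[j, i] <- mean(abs(dos[i, ok] - dos[j, ok]) / 2)
  }
  D
}

# exact two-sided Hardy-Weinberg test (Wigginton et al. enumeration)
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  probs <- numeric(rare + 1)
  # P(n_ab heterozygotes | allele counts), recursive enumeration
  mid <- rare * (2 * n - rare) / (2 * n)
  mid <- floor(mid)
  if ((mid %% 2) != (rare %% 2)) mid <- mid + 1
  probs[mid + 1] <- 1
  het <- mid
  while (het > 1) {
    hom_r <- (rare - het) / 2
    hom_c <- n - het - hom_r
    probs[het - 2 + 1] <- probs[het + 1] * het * (het - 1) /
      (4 * (hom_r + 1) * (hom_c + 1))
    het <- het - 2
  }
  het <- mid
  while (het <= rare - 2) {
    hom_r <- (rare - het) / 2
    hom_c <- n - het - hom_r
    probs[het + 2 + 1] <- probs[het + 1] * 4 * hom_r * hom_c /
      ((het + 2) * (het + 1))
    het <- het + 2
  }
  probs <- probs / sum(probs)
  obs_het <- n_ab
  sum(probs[probs <= probs[obs_het + 1] + 1e-12])
}

# path-length distance matrix of a random tree with positive branch lengths
additive_matrix <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}

# independent rule oracle for the ternary classification
oracle_ternary <- function(q) {
  anc <- c("C", "S", "M")
  if (max(q) > 0.80) return(anc[which.max(q)])
  if (min(q) <= 0.10) {
    # smallest component dropped; on ties keep the earlier (C>S>M priority)
    mins <- which(q == min(q))
    drop <- mins[length(mins)]
    keep <- sort(setdiff(1:3, drop))
    return(c(CS = "CS", CM = "MC", SM = "SM")[paste0(anc[keep],
                                                     collapse = "")])
  }
  "MCS"
}

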