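#' Chromosome-wide PCA
#'
#' [gm_pca()] restricted to one chromosome; at an SV the leading axes show
#' three separated clusters (the two homokaryote groups and the
#' heterokaryotes between them).
#'
#' @param gm a [genotype_matrix()].
#' @param chrom chromosome id.
#' @param n_axes axes to return.
#' @param scaling see [gm_pca()].
#' @export
chrom_pca <- function(gm, chrom, n_axes = 4,
                      scaling = c("patterson", "unit", "none")) {
  gm_pca(gm_region(gm, chrom), n_axes = n_axes, scaling = match.arg(scaling))
}

# internal: deterministic 1-D Gaussian mixture EM with unequal variances.
# Initialized from quantile-seeded k-means (no RNG), E-step in log space, a
# variance floor against zero-width clusters. BIC on the "larger is better"
# convention. Returns NULL on degenerate input.
.mix1d <- function(x, G, max_iter = 300, tol = 1e-8) {
  n <- length(x)
  if (n < G + 1) return(NULL)
  if (G == 1) {
    mu <- mean(x)
    s <- max(stats::sd(x), 1e-9)
    ll <- sum(stats::dnorm(x, mu, s, log = TRUE))
    return(list(G = 1L, mean = mu, sd = s, weight = 1,
                loglik = ll, bic = 2 * ll - 2 * log(n),
                z = matrix(1, n, 1), classification = rep(1L, n)))
  }
  v_floor <- max(stats::var(x), 1e-12) * 1e-8
  run_em <- function(ctr) {
    cl0 <- apply(abs(outer(x, ctr, `-`)), 1, which.min)
    mu <- vapply(seq_len(G), function(g) {
      xx <- x[cl0 == g]
      if (length(xx)) mean(xx) else ctr[g]
    }, 0)
    v <- vapply(seq_len(G), function(g) {
      xx <- x[cl0 == g]
      if (length(xx) > 1) stats::var(xx) else stats::var(x) / G^2
    }, 0)
    v <- pmax(v, v_floor)
    w <- pmax(tabulate(cl0, G), 0.5) / n
    w <- w / sum(w)
    ll_old <- -Inf
    z <- NULL
    ll <- -Inf
    for (it in seq_len(max_iter)) {
      logd <- vapply(seq_len(G), function(g) {
        log(w[g]) + stats::dnorm(x, mu[g], sqrt(v[g]), log = TRUE)
      }, numeric(n))
      m <- apply(logd, 1, max)
      z <- exp(logd - m)
      rs <- rowSums(z)
      z <- z / rs
      ll <- sum(m + log(rs))
      nk <- colSums(z)
      if (any(nk < 1e-8)) return(NULL)
      w <- nk / n
      mu <- colSums(z * x) / nk
      v <- pmax(vapply(seq_len(G), function(g) {
        sum(z[, g] * (x - mu[g])^2) / nk[g]
      }, 0), v_floor)
      if (is.finite(ll) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(mean = mu, sd = sqrt(v), weight = w, loglik = ll, z = z)
  }
  # two deterministic inits: data quantiles (balanced clusters) and centers
  # equispaced over the range (one dominant cluster); keep the better mode
  ctr_q <- stats::quantile(x, (2 * seq_len(G) - 1) / (2 * G), names = FALSE)
  ctr_r <- min(x) + (2 * seq_len(G) - 1) / (2 * G) * (max(x) - min(x))
  fits <- list()
  if (length(unique(ctr_q)) == G) fits <- c(fits, list(run_em(ctr_q)))
  if (length(unique(ctr_r)) == G) fits <- c(fits, list(run_em(ctr_r)))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) return(NULL)
  best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  npar <- 3 * G - 1
  list(G = as.integer(G), mean = best$mean, sd = best$sd,
       weight = best$weight, loglik = best$loglik,
       bic = 2 * best$loglik - npar * log(n), z = best$z,
       classification = max.col(best$z, ties.method = "first"))
}

#' Select the PCA axis carrying the SV signal
#'
#' Among the leading axes, chooses the one maximizing a three-cluster
#' separation score (difference between the three- and one-component
#' Gaussian-mixture BIC on the axis scores) whose middle cluster also shows
#' elevated heterozygosity (heterokaryotes are heterozygous at every fixed
#' difference). Returns `NA` when no axis passes both checks.
#'
#' @param pca a [gm_pca()] result (typically from [chrom_pca()]).
#' @param het_by_sample named per-sample heterozygosity (see
#'   [individual_het()]), computed on the same chromosome.
#' @param max_axes leading axes to examine.
#' @param het_ratio minimum ratio of middle-cluster to outer-cluster mean
#'   heterozygosity.
#' @param symmetry middle-component position tolerance: its mean must lie
#'   within this fraction of the outer-component span from their midpoint
#'   (heterokaryotes sit halfway between homokaryote clusters on a dosage
#'   axis; a geographic axis does not have this property).
#' @return Integer axis index, or `NA_integer_` if none qualifies.
#' @export
select_sv_axis <- function(pca, het_by_sample, max_axes = 4,
                           het_ratio = 1.1, symmetry = 0.25) {
  het <- het_by_sample[rownames(pca$coords)]
  best_axis <- NA_integer_
  best_score <- -Inf
  for (j in seq_len(min(max_axes, ncol(pca$coords)))) {
    x <- pca$coords[, j]
    fit3 <- .mix1d(x, 3)
    fit1 <- .mix1d(x, 1)
    if (is.null(fit3) || is.null(fit1)) next
    score <- fit3$bic - fit1$bic      # BIC here: larger is better
    if (!is.finite(score) || score <= 0) next
    ord <- order(fit3$mean)
    cl <- match(fit3$classification, ord)   # 1 = low, 2 = middle, 3 = high
    if (min(table(factor(cl, levels = 1:3))) < 1) next
    mu <- sort(fit3$mean)
    if (abs(mu[2] - (mu[1] + mu[3]) / 2) > symmetry * (mu[3] - mu[1])) next
    mid_het <- mean(het[cl == 2], na.rm = TRUE)
    out_het <- mean(het[cl != 2], na.rm = TRUE)
    if (!is.finite(mid_het) || !is.finite(out_het)) next
    if (mid_het <= het_ratio * out_het) next
    if (score > best_score) {
      best_score <- score
      best_axis <- j
    }
  }
  best_axis
}

#' Genotype karyotypes from PCA cluster membership
#'
#' Fits a three-component 1-D Gaussian mixture to the scores of the selected
#' axis; each sample is called by its MAP component when the posterior
#' exceeds `threshold`, otherwise left unassigned. The middle component is
#' the heterokaryote class; the outer components carry the provisional
#' labels `00` (lower scores) and `11` (higher scores) until [polarize()]
#' fixes their orientation.
#'
#' Samples far from every component (more than `outlier_sd` standard
#' deviations from their MAP component's mean) are also left unassigned:
#' they sit between clusters without clear membership.
#'
#' @param pca a [gm_pca()] result.
#' @param axis axis index (see [select_sv_axis()]).
#' @param threshold posterior required for a call.
#' @param outlier_sd maximum z-distance from the assigned component.
#' @return data.frame `sample_id, genotype, confidence, axis_used` of class
#'   `karyotype_calls`; genotype in `{00, 01, 11, unassigned}`.
#' @export
genotype_karyotypes <- function(pca, axis, threshold = 0.90,
                                outlier_sd = 4) {
  x <- pca$coords[, axis]
  fit <- .mix1d(x, 3)
  out <- data.frame(sample_id = rownames(pca$coords),
                    genotype = "unassigned",
                    confidence = NA_real_, axis_used = axis,
                    stringsAsFactors = FALSE, row.names = NULL)
  degenerate <- TRUE
  if (!is.null(fit)) {
    post <- fit$z
    ord <- order(fit$mean)
    labels <- c("00", "01", "11")[match(seq_len(3), ord)]
    map <- apply(post, 1, which.max)
    conf <- post[cbind(seq_along(map), map)]
    zdist <- abs(x - fit$mean[map]) / fit$sd[map]
    called <- conf > threshold & zdist <= outlier_sd
    counts <- table(factor(labels[map][called], levels = c("00", "01", "11")))
    degenerate <- any(table(factor(labels[map], levels = c("00", "01", "11")))
                      < 2)
    if (!degenerate) {
      out$genotype[called] <- labels[map][called]
      out$confidence <- conf
    }
  }
  if (degenerate) {
    warning("degenerate mixture fit (a component holds < 2 samples); ",
            "all samples left unassigned")
    out$genotype <- "unassigned"
    out$confidence <- NA_real_
  }
  class(out) <- c("karyotype_calls", "data.frame")
  out
}

#' Polarize karyotype labels by southern ancestry
#'
#' The homokaryote cluster containing the most S-class samples becomes `00`
#' (and the other `11`), anchoring the `0` haplotype to the southern
#' lineage. With no S-class samples, or a tie, labels are kept as-is and the
#' result is flagged unpolarized.
#'
#' @param calls a `karyotype_calls` data.frame.
#' @param profiles ancestry profiles (see [ancestry_profiles()]) with
#'   `sample_id` and `class`.
#' @return `calls`, possibly with `00`/`11` swapped, plus attributes
#'   `polarized` (logical) and `evidence` (S-class counts per homokaryote
#'   cluster).
#' @export
polarize <- function(calls, profiles) {
  cls <- profiles$class[match(calls$sample_id, profiles$sample_id)]
  s00 <- sum(cls == "S" & calls$genotype == "00", na.rm = TRUE)
  s11 <- sum(cls == "S" & calls$genotype == "11", na.rm = TRUE)
  evidence <- c(`00` = s00, `11` = s11)
  if (s00 == s11) {
    attr(calls, "polarized") <- FALSE
    attr(calls, "evidence") <- evidence
    return(calls)
  }
  if (s11 > s00) {
    g <- calls$genotype
    calls$genotype[g == "00"] <- "11"
    calls$genotype[g == "11"] <- "00"
    evidence <- c(`00` = s11, `11` = s00)
  }
  attr(calls, "polarized") <- TRUE
  attr(calls, "evidence") <- evidence
  calls
}

#' Local PCA field over genomic windows
#'
#' Per non-overlapping window, the top-k eigenstructure of the sample
#' covariance of centred dosages (mean-imputed); window-pair distance is the
#' Frobenius distance between the trace-normalized rank-k covariance
#' approximations, followed by classical MDS.
#'
#' @param gm a [genotype_matrix()].
#' @param chrom chromosome id.
#' @param window window size in bp.
#' @param k rank of the window covariance approximation.
#' @param min_sites minimum polymorphic sites for a window to enter the
#'   field.
#' @param mds_axes MDS dimensions.
#' @return Object of class `local_pca_field`: `windows` (window table of the
#'   retained windows), `dist` (symmetric matrix), `mds` (coordinates),
#'   `eigen` (per-window eigenvalues).
#' @export
local_pca <- function(gm, chrom, window = 5000, k = 2, min_sites = 15,
                      mds_axes = 2) {
  g <- gm_region(gm, chrom)
  w <- make_windows(g$sites, size = window, min_sites = min_sites)
  widx <- .site_window(g, w)
  reps <- list()
  kept <- integer()
  for (i in which(w$usable)) {
    d <- g$dosage[, which(widx == i), drop = FALSE]
    mu <- colMeans(d, na.rm = TRUE)
    x <- sweep(d, 2, mu)
    x[is.na(x)] <- 0
    poly <- apply(x, 2, function(v) any(v != 0))
    x <- x[, poly, drop = FALSE]
    if (ncol(x) < min_sites) next
    sv <- svd(x, nu = min(k, ncol(x)), nv = 0)
    lam <- sv$d^2
    total <- sum(lam)
    if (total <= 0) next
    kk <- min(k, length(lam))
    reps[[length(reps) + 1]] <- list(U = sv$u[, seq_len(kk), drop = FALSE],
                                     lam = lam[seq_len(kk)] / total)
    kept <- c(kept, i)
  }
  W <- length(reps)
  if (W < 2) stop("fewer than 2 usable windows on ", chrom)
  D <- matrix(0, W, W)
  for (a in seq_len(W - 1)) {
    for (b in (a + 1):W) {
      ra <- reps[[a]]; rb <- reps[[b]]
      cross <- crossprod(ra$U, rb$U)            # k x k
      d2 <- sum(ra$lam^2) + sum(rb$lam^2) -
        2 * sum((ra$lam %o% rb$lam) * cross^2)
      D[a, b] <- D[b, a] <- sqrt(max(d2, 0))
    }
  }
  mds <- stats::cmdscale(D, k = min(mds_axes, W - 1))
  structure(list(windows = w[kept, , drop = FALSE], dist = D, mds = mds,
                 eigen = t(vapply(reps, function(r) r$lam, numeric(k)))),
            class = "local_pca_field")
}

#' Partition local-PCA windows into SV-like and background clusters
#'
#' Two-means clustering of the MDS coordinates; the minority cluster (SV
#' windows are a minority of the chromosome) is labelled the SV cluster,
#' with ties broken toward the cluster farther from the origin.
#'
#' @param field a [local_pca()] result.
#' @return Logical vector over `field$windows`: `TRUE` for SV-cluster
#'   membership.
#' @export
local_field_clusters <- function(field) {
  m <- as.matrix(field$mds)
  km <- stats::kmeans(m, centers = 2, nstart = 10)
  sizes <- tabulate(km$cluster, 2)
  sv <- if (sizes[1] != sizes[2]) which.min(sizes) else
    which.max(rowSums(km$centers^2))
  km$cluster == sv
}

#' Delimit SV blocks from flagged windows
#'
#' A block is a maximal run of windows carrying a `q95` flag and/or
#' local-PCA SV-cluster membership, allowing interior gaps of at most `gap`
#' unflagged windows; the block is the union span of the run.
#'
#' @param stat_table a flagged window table for one chromosome (see
#'   [quantile_flags()]).
#' @param local_field optional [local_pca()] result for the same chromosome;
#'   its SV-cluster windows (see [local_field_clusters()]) are OR-ed with
#'   the flags.
#' @param gap maximum run of unflagged windows bridged inside a block.
#' @return data.frame `chrom, start, end, n_windows`; zero rows when nothing
#'   is flagged.
#' @export
delimit_block <- function(stat_table, local_field = NULL, gap = 2) {
  ch <- unique(stat_table$chrom)
  stopifnot(length(ch) == 1)
  st <- stat_table[order(stat_table$start), , drop = FALSE]
  ind <- st$flag %in% c("q95", "q99")
  if (!is.null(local_field)) {
    member <- local_field_clusters(local_field)
    mw <- local_field$windows[member, , drop = FALSE]
    ind <- ind | (st$start %in% mw$start)
  }
  hits <- which(ind)
  if (length(hits) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      stringsAsFactors = FALSE))
  }
  brk <- c(0, cumsum(diff(hits) > gap + 1))
  blocks <- lapply(split(hits, brk), function(ii) {
    data.frame(chrom = ch, start = st$start[min(ii)], end = st$end[max(ii)],
               n_windows = max(ii) - min(ii) + 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(blocks, list(make.row.names = FALSE)))
}

#' Genotype and haplotype frequency tables per ancestry cluster
#'
#' For each parental cluster (classes C, S, M; optionally split by a
#' sample-sheet column) the frequencies of the `00`/`01`/`11` genotypes
#' among called samples, plus the `0` haplotype frequency
#' `(2 n00 + n01) / (2 n_called)`. Unassigned samples are excluded from all
#' denominators.
#'
#' @param calls a `karyotype_calls` data.frame (after [polarize()]).
#' @param profiles ancestry profiles with `sample_id` and `class`.
#' @param sample_sheet optional sheet with `sample_id` and `location`; when
#'   given, clusters are split by location.
#' @return data.frame `cluster, [location,] n_called, f00, f01, f11,
#'   hap0_freq`.
#' @export
freq_tables <- function(calls, profiles, sample_sheet = NULL) {
  cls <- profiles$class[match(calls$sample_id, profiles$sample_id)]
  keep <- cls %in% c("C", "S", "M") & calls$genotype != "unassigned"
  d <- data.frame(cluster = cls[keep], genotype = calls$genotype[keep],
                  sample_id = calls$sample_id[keep],
                  stringsAsFactors = FALSE)
  if (!is.null(sample_sheet)) {
    d$location <- sample_sheet$location[match(d$sample_id,
                                              sample_sheet$sample_id)]
    sp <- split(d, list(d$cluster, d$location), drop = TRUE)
  } else {
    sp <- split(d, d$cluster)
  }
  rows <- lapply(sp, function(g) {
    n <- nrow(g)
    n00 <- sum(g$genotype == "00"); n01 <- sum(g$genotype == "01")
    n11 <- sum(g$genotype == "11")
    out <- data.frame(cluster = g$cluster[1], n_called = n,
                      f00 = n00 / n, f01 = n01 / n, f11 = n11 / n,
                      hap0_freq = (2 * n00 + n01) / (2 * n),
                      stringsAsFactors = FALSE)
    if (!is.null(g$location)) out <- cbind(location = g$location[1], out)
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Scan for a third haplotype within the derived haplogroup
#'
#' Within the `11` homokaryotes, re-runs PCA and a 1-D Gaussian-mixture
#' model comparison on the leading axis: a supported secondary split (e.g.
#' coastal-`1` versus marine-`1`) is reported when a multi-component model
#' beats the single-component model by BIC.
#'
#' @param gm a [genotype_matrix()].
#' @param calls karyotype calls for the chromosome.
#' @param chrom chromosome id.
#' @param region optional `list(start=, end=)` restricting to the SV block.
#' @param min_samples minimum `11` samples for the scan.
#' @return List with `status` (`"ok"` or `"insufficient data"`), `detected`,
#'   `bic_margin`, `n_groups` and per-sample `subgroup` assignments (ordered
#'   along the axis).
#' @export
third_haplotype_scan <- function(gm, calls, chrom, region = NULL,
                                 min_samples = 6) {
  ids <- calls$sample_id[calls$genotype == "11"]
  if (length(ids) < min_samples) {
    return(list(status = "insufficient data", detected = FALSE,
                bic_margin = NA_real_, n_groups = 0L, subgroup = NULL))
  }
  g <- gm_region(gm, chrom, (region$start %||% 0L), (region$end %||% Inf))
  g <- gm_subset(g, samples = ids)
  pca <- tryCatch(gm_pca(g, n_axes = 2), error = function(e) NULL)
  if (is.null(pca)) {
    return(list(status = "insufficient data", detected = FALSE,
                bic_margin = NA_real_, n_groups = 0L, subgroup = NULL))
  }
  x <- pca$coords[, 1]
  fit1 <- .mix1d(x, 1)
  cand <- Filter(Negate(is.null), list(.mix1d(x, 2), .mix1d(x, 3)))
  if (length(cand) == 0 || is.null(fit1)) {
    return(list(status = "ok", detected = FALSE, bic_margin = -Inf,
                n_groups = 1L,
                subgroup = stats::setNames(rep(1L, length(ids)), ids)))
  }
  fitm <- cand[[which.max(vapply(cand, `[[`, 0, "bic"))]]
  margin <- fitm$bic - fit1$bic
  # a supported split needs BIC preference plus well-separated components
  # that each hold at least two samples
  ord0 <- order(fitm$mean)
  mu <- fitm$mean[ord0]; sds <- fitm$sd[ord0]
  gaps <- diff(mu) / vapply(seq_len(length(mu) - 1), function(i) {
    max(sds[i], sds[i + 1], 1e-12)
  }, 0)
  sizes <- tabulate(match(fitm$classification, ord0), length(mu))
  detected <- is.finite(margin) && margin > 0 && all(gaps > 4) &&
    all(sizes >= 2)
  ord <- order(fitm$mean)
  sub <- match(fitm$classification, ord)
  list(status = "ok", detected = detected, bic_margin = margin,
       n_groups = if (detected) fitm$G else 1L,
       subgroup = stats::setNames(if (detected) sub else
         rep(1L, length(ids)), ids))
}

#' Detect, genotype and polarize SVs on flagged chromosomes
#'
#' Orchestrates the per-chromosome SV workflow: chromosome-wide PCA, axis
#' selection against per-chromosome heterozygosity, Gaussian-mixture
#' karyotype calls, southern-ancestry polarization, block delimitation from
#' the flagged window table (optionally refined by local PCA), and frequency
#' tables.
#'
#' @param gm a [genotype_matrix()].
#' @param profiles ancestry profiles (see [ancestry_profiles()]).
#' @param flagged_chroms chromosomes to process (see
#'   [chromosome_sv_flag()]).
#' @param stat_table flagged window table covering those chromosomes.
#' @param posterior call threshold for [genotype_karyotypes()].
#' @param use_local_pca also run [local_pca()] per chromosome for block
#'   delimitation.
#' @param sample_sheet optional sheet for location-split frequency tables.
#' @return Named list (per chromosome) of `sv_call` objects: `chrom`,
#'   `axis`, `calls`, `polarized`, `evidence`, `block`, `freq_table`.
#' @export
sv_scan <- function(gm, profiles, flagged_chroms, stat_table,
                    posterior = 0.90, use_local_pca = FALSE,
                    sample_sheet = NULL) {
  out <- list()
  for (ch in flagged_chroms) {
    st0 <- stat_table[stat_table$chrom == ch, , drop = FALSE]
    fw <- st0[st0$flag %in% c("q95", "q99"), , drop = FALSE]
    # heterozygosity over the flagged windows: heterokaryotes are
    # heterozygous at every fixed difference, so the contrast with the
    # homokaryote clusters is strongest inside the candidate region
    if (nrow(fw) > 0) {
      g <- gm_region(gm, ch)
      idx <- .site_window(g, fw)
      g <- gm_subset(g, sites = !is.na(idx))
      het <- individual_het(g)
      pca <- gm_pca(g, n_axes = 4)
    } else {
      het <- individual_het(gm, region = list(chrom = ch))
      pca <- chrom_pca(gm, ch)
    }
    axis <- select_sv_axis(pca, het)
    if (is.na(axis)) {
      out[[ch]] <- list(chrom = ch, axis = NA_integer_, calls = NULL,
                        polarized = FALSE, evidence = NULL, block = NULL,
                        freq_table = NULL)
      next
    }
    calls <- genotype_karyotypes(pca, axis, threshold = posterior)
    calls <- polarize(calls, profiles)
    st <- stat_table[stat_table$chrom == ch, , drop = FALSE]
    field <- if (use_local_pca) local_pca(gm, ch) else NULL
    block <- delimit_block(st, field)
    out[[ch]] <- structure(
      list(chrom = ch, axis = axis, calls = calls,
           polarized = isTRUE(attr(calls, "polarized")),
           evidence = attr(calls, "evidence"), block = block,
           freq_table = freq_tables(calls, profiles, sample_sheet)),
      class = "sv_call")
  }
  out
}

#' @export
print.sv_call <- function(x, ...) {
  tab <- table(x$calls$genotype)
  cat("SV call on", x$chrom, "(axis PC", x$axis, "):",
      paste(names(tab), tab, sep = "=", collapse = " "),
      if (x$polarized) "[polarized]" else "[unpolarized]", "\n")
  invisible(x)
}
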