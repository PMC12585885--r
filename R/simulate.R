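#' Specification of one simulated structural variant
#'
#' Describes a non-recombining SV block: its location, the number of
#' segregating haplotypes (2, or 3 when a northern sub-split of the derived
#' haplogroup exists), the per-bp fixed-difference density between alternate
#' haplotypes, and the per-lineage haplotype frequencies.
#'
#' @param chrom chromosome id.
#' @param start,end block interval, 0-based half-open bp.
#' @param hap_divergence target per-bp fixed-difference density between the
#'   `0` and `1` haplogroups (the realized homokaryote d_XY is slightly
#'   higher because of shared low-frequency polymorphism).
#' @param karyotype_freqs per-lineage haplotype frequencies: either a numeric
#'   vector of length 3 (frequency of haplotype `0` in lineages C, S, M; a
#'   two-haplotype SV), or a 3 x n_hap matrix with rows C, S, M and columns
#'   `0`, `1a`, `1b` for a three-haplotype SV. Rows must sum to 1.
#' @param sub_divergence for three-haplotype SVs, the per-bp difference
#'   density between the `1a` and `1b` sub-haplotypes, as a fraction of
#'   `hap_divergence` (default 0.4: the northern sub-split is younger).
#' @param region_site_density total site density (sites/bp) inside the block;
#'   `NULL` matches the chromosome's collinear density so windowed statistics
#'   keep enough sites per window.
#' @return An object of class `sv_spec`.
#' @export
sv_spec <- function(chrom, start, end, hap_divergence, karyotype_freqs,
                    sub_divergence = 0.4, region_site_density = NULL) {
  stopifnot(end > start, hap_divergence >= 0)
  if (is.null(dim(karyotype_freqs))) {
    stopifnot(length(karyotype_freqs) == 3)
    karyotype_freqs <- cbind(`0` = karyotype_freqs, `1` = 1 - karyotype_freqs)
    rownames(karyotype_freqs) <- c("C", "S", "M")
  }
  stopifnot(nrow(karyotype_freqs) == 3,
            ncol(karyotype_freqs) %in% c(2, 3),
            all(karyotype_freqs >= 0), all(karyotype_freqs <= 1),
            all(abs(rowSums(karyotype_freqs) - 1) < 1e-8))
  if (is.null(rownames(karyotype_freqs)))
    rownames(karyotype_freqs) <- c("C", "S", "M")
  if (is.null(colnames(karyotype_freqs)))
    colnames(karyotype_freqs) <-
      if (ncol(karyotype_freqs) == 2) c("0", "1") else c("0", "1a", "1b")
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end),
                 n_haplotypes = ncol(karyotype_freqs),
                 hap_divergence = hap_divergence,
                 sub_divergence = sub_divergence,
                 karyotype_freqs = karyotype_freqs,
                 region_site_density = region_site_density),
            class = "sv_spec")
}

#' Simulation configuration
#'
#' @param n_per_group named counts for the three parental classes `C`, `S`,
#'   `M` and the admixed classes `CS`, `SM`, `MC`, `MCS`.
#' @param n_chroms number of chromosomes.
#' @param sites_per_chrom collinear SNPs per chromosome.
#' @param chrom_length_bp chromosome length in bp.
#' @param fst_targets named pairwise Hudson F_ST targets `CM`, `CS`, `SM`
#'   between the parental lineages; solved into per-lineage Balding-Nichols
#'   drift parameters.
#' @param sv_specs list of [sv_spec()] objects.
#' @param seed integer; the whole simulation is reproducible byte-for-byte
#'   given the config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c(C = 30, S = 30, M = 30,
                                       CS = 20, SM = 20, MC = 20, MCS = 30),
                       n_chroms = 4, sites_per_chrom = 2000,
                       chrom_length_bp = 1e6,
                       fst_targets = c(CM = 0.013, CS = 0.075, SM = 0.066),
                       sv_specs = list(), seed = 1L) {
  need <- c("C", "S", "M", "CS", "SM", "MC", "MCS")
  stopifnot(all(need %in% names(n_per_group)),
            all(n_per_group >= 0), n_chroms >= 1, sites_per_chrom >= 1,
            all(c("CM", "CS", "SM") %in% names(fst_targets)))
  FF <- lineage_drift(fst_targets)  # errors if infeasible
  chroms <- sprintf("chr%02d", seq_len(n_chroms))
  for (sv in sv_specs) {
    stopifnot(inherits(sv, "sv_spec"))
    if (!sv$chrom %in% chroms) stop("SV chromosome not in genome: ", sv$chrom)
    if (sv$end > chrom_length_bp) stop("SV region beyond chromosome end")
  }
  structure(list(n_per_group = n_per_group[need], n_chroms = n_chroms,
                 sites_per_chrom = sites_per_chrom,
                 chrom_length_bp = as.integer(chrom_length_bp),
                 fst_targets = fst_targets, lineage_F = FF,
                 sv_specs = sv_specs, seed = as.integer(seed),
                 chroms = chroms),
            class = "sim_config")
}

#' Solve pairwise F_ST targets into per-lineage drift parameters
#'
#' Under independent Balding-Nichols drift of each lineage from a shared
#' ancestor, the expected Hudson F_ST (ratio of averages, with sampling
#' correction) between lineages a and b is `(F_a + F_b) / 2`. The three
#' pairwise targets therefore determine the per-lineage parameters by a
#' linear solve; an infeasible triple (any `F` outside `(0, 1)`) is an error.
#'
#' @param fst_targets named vector with elements `CM`, `CS`, `SM`.
#' @return Named vector `c(C=, S=, M=)` of drift parameters.
#' @export
lineage_drift <- function(fst_targets) {
  t_cm <- fst_targets[["CM"]]; t_cs <- fst_targets[["CS"]]
  t_sm <- fst_targets[["SM"]]
  FF <- c(C = t_cm + t_cs - t_sm, S = t_cs + t_sm - t_cm,
          M = t_cm + t_sm - t_cs)
  if (any(FF <= 0) || any(FF >= 1)) {
    stop("infeasible pairwise F_ST targets: per-lineage drift would be ",
         paste(sprintf("%s=%.4f", names(FF), FF), collapse = ", "),
         "; each pairwise target must be below the sum of the other two ",
         "and the implied drift must lie in (0, 1)")
  }
  FF
}

# internal: draw Balding-Nichols lineage frequencies for one drift parameter
.bn_freq <- function(p_anc, F) {
  if (F <= 0) return(p_anc)
  a <- p_anc * (1 - F) / F
  b <- (1 - p_anc) * (1 - F) / F
  stats::rbeta(length(p_anc), a, b)
}

# internal: draw admixture proportions for one class label
.draw_q <- function(class) {
  switch(class,
    C = c(1, 0, 0), S = c(0, 1, 0), M = c(0, 0, 1),
    CS = .q_pair(1, 2), SM = .q_pair(2, 3), MC = .q_pair(3, 1),
    MCS = .q_three())
}

.q_pair <- function(i, j) {
  u <- stats::runif(1, 0, 0.08)        # minor third ancestry, <= 0.10
  w <- stats::runif(1, 0.25, 0.75)     # split of the dominant pair
  q <- rep(u / 1, 3)
  q[i] <- w * (1 - u); q[j] <- (1 - w) * (1 - u)
  q[-c(i, j)] <- u
  q
}

.q_three <- function() {
  repeat {
    g <- stats::rgamma(3, shape = 8)
    q <- g / sum(g)
    if (min(q) > 0.10 && max(q) <= 0.80) return(q)
  }
}

#' Simulate the collinear (freely recombining) genome
#'
#' Balding-Nichols scheme: per site an ancestral frequency
#' `p ~ Uniform(0.05, 0.95)`; each lineage's frequency is Beta-distributed
#' around `p` with its drift parameter; an individual's site-wise allele
#' frequency is the ancestry-weighted mixture of lineage frequencies and its
#' genotype is Binomial(2, .).
#'
#' @param config a [sim_config()].
#' @return `list(gm = genotype_matrix, truth = truth table)`. The truth table
#'   carries per-sample ancestry proportions and class labels, the lineage
#'   drift parameters and (empty) SV slots filled by [simulate_sv()].
#' @export
simulate_collinear <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  npg <- config$n_per_group
  classes <- rep(names(npg), npg)
  n <- length(classes)
  sample_id <- sprintf("%s_%03d", classes, stats::ave(seq_len(n), classes,
                                                      FUN = seq_along))
  Q <- t(vapply(classes, .draw_q, numeric(3)))
  colnames(Q) <- c("C", "S", "M")
  rownames(Q) <- sample_id

  FF <- config$lineage_F
  L <- config$sites_per_chrom
  dos_list <- vector("list", config$n_chroms)
  site_list <- vector("list", config$n_chroms)
  bases <- c("A", "C", "G", "T")
  for (ci in seq_len(config$n_chroms)) {
    pos <- sort(sample.int(config$chrom_length_bp, L))
    p_anc <- stats::runif(L, 0.05, 0.95)
    P <- rbind(C = .bn_freq(p_anc, FF["C"]),
               S = .bn_freq(p_anc, FF["S"]),
               M = .bn_freq(p_anc, FF["M"]))
    f <- Q %*% P                      # n x L individual allele frequencies
    dos_list[[ci]] <- matrix(stats::rbinom(n * L, 2L, f), n, L)
    ref <- sample(bases, L, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    site_list[[ci]] <- data.frame(chrom = config$chroms[ci], pos = pos,
                                  ref = ref, alt = unname(alt),
                                  stringsAsFactors = FALSE)
  }
  gm <- genotype_matrix(do.call(cbind, dos_list),
                        do.call(rbind, site_list), sample_id)
  truth <- list(
    samples = data.frame(sample_id = sample_id, class = classes,
                         q_C = Q[, "C"], q_S = Q[, "S"], q_M = Q[, "M"],
                         stringsAsFactors = FALSE, row.names = NULL),
    lineage_F = FF,
    svs = data.frame(chrom = character(), start = integer(), end = integer(),
                     n_haplotypes = integer(), hap_divergence = numeric(),
                     stringsAsFactors = FALSE),
    karyotypes = data.frame(sample_id = character(), chrom = character(),
                            hap1 = character(), hap2 = character(),
                            karyotype = character(),
                            karyotype_main = character(),
                            stringsAsFactors = FALSE),
    config = config
  )
  list(gm = gm, truth = truth)
}

#' Overlay a non-recombining SV block on a simulated genome
#'
#' Inside the block, existing collinear sites are replaced by
#' haplotype-structured sites: fixed inter-haplogroup differences at density
#' `hap_divergence`, shared low-frequency polymorphism padding the block to
#' `region_site_density`, and (for three-haplotype SVs) fixed differences
#' between the `1a`/`1b` sub-haplotypes. Each individual draws two haplotype
#' labels from its ancestry-weighted haplotype frequencies; every fixed site
#' is fully determined by the drawn labels, so heterokaryotes are
#' heterozygous at all fixed differences and there is no recombination within
#' the block.
#'
#' @param gm genotype matrix from [simulate_collinear()].
#' @param truth matching truth table (updated and returned).
#' @param spec an [sv_spec()].
#' @return `list(gm =, truth =)` with the block applied.
#' @export
simulate_sv <- function(gm, truth, spec) {
  stopifnot(inherits(spec, "sv_spec"))
  prev <- truth$svs[truth$svs$chrom == spec$chrom, , drop = FALSE]
  if (nrow(prev) && any(pmax(prev$start, spec$start) <
                        pmin(prev$end, spec$end))) {
    stop("SV region overlaps a previously simulated SV on ", spec$chrom)
  }
  chrom_sites <- gm$sites$chrom == spec$chrom
  if (!any(chrom_sites)) stop("no sites on chromosome ", spec$chrom)
  span <- spec$end - spec$start
  dens <- spec$region_site_density
  if (is.null(dens)) {
    dens <- sum(chrom_sites) / max(gm$sites$pos[chrom_sites])
  }
  n_fix <- round(spec$hap_divergence * span)
  three <- spec$n_haplotypes == 3
  # site budget: for 3 haplotypes, carve the 1a/1b differences out of the
  # 0-vs-1 set so that d(0,1a) = d(0,1b) = hap_divergence and
  # d(1a,1b) = sub_divergence * hap_divergence
  n_sub <- if (three) round(spec$sub_divergence / 2 * n_fix) else 0L
  n_common <- n_fix - n_sub
  n_fix_total <- n_common + 2L * n_sub
  n_poly <- max(0L, round(dens * span) - n_fix_total)
  n_new <- n_fix_total + n_poly
  if (n_new > span) stop("SV region too small for requested site density")
  pos_new <- spec$start + sort(sample.int(span, n_new))  # 1-based in (start, end]
  type <- sample(rep(c("common", "a_only", "b_only", "poly"),
                     c(n_common, n_sub, n_sub, n_poly)))
  # haplotype consensus: rows = haplotypes, entries = alt-allele indicator
  haps <- if (three) c("0", "1a", "1b") else c("0", "1")
  H <- matrix(0L, length(haps), n_new, dimnames = list(haps, NULL))
  H["0", ] <- 0L
  if (three) {
    H["1a", type %in% c("common", "a_only")] <- 1L
    H["1b", type %in% c("common", "b_only")] <- 1L
  } else {
    H["1", type == "common"] <- 1L
  }
  f_poly <- stats::runif(n_new, 0.005, 0.06)  # shared ancestral low-freq poly

  # draw two haplotype labels per individual from ancestry-weighted freqs
  Q <- as.matrix(truth$samples[, c("q_C", "q_S", "q_M")])
  hp <- Q %*% spec$karyotype_freqs[c("C", "S", "M"), , drop = FALSE]
  n <- nrow(Q)
  draw <- function() haps[apply(hp, 1, function(p) sample.int(length(haps), 1,
                                                              prob = p))]
  h1 <- draw(); h2 <- draw()
  dos <- H[h1, , drop = FALSE] + H[h2, , drop = FALSE]
  is_poly <- type == "poly"
  np <- sum(is_poly)
  if (np > 0) {
    dos[, is_poly] <- matrix(
      stats::rbinom(n * np, 2L, rep(f_poly[is_poly], each = n)), n, np)
  }

  # splice the block into the genotype matrix
  in_region <- chrom_sites & gm$sites$pos > spec$start &
    gm$sites$pos <= spec$end
  keep <- which(!in_region)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_new, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  new_sites <- data.frame(chrom = spec$chrom, pos = pos_new, ref = ref,
                          alt = unname(alt), stringsAsFactors = FALSE)
  sites <- rbind(gm$sites[keep, c("chrom", "pos", "ref", "alt")], new_sites)
  dosage <- cbind(gm$dosage[, keep, drop = FALSE], dos)
  ord <- order(match(sites$chrom, truth$config$chroms), sites$pos)
  gm2 <- genotype_matrix(dosage[, ord, drop = FALSE], sites[ord, ],
                         gm$samples)

  # ground truth
  sw <- function(h) ifelse(h == "0", "0", "1")
  pair <- function(a, b) paste0(pmin(a, b), pmax(a, b))
  truth$svs <- rbind(truth$svs,
    data.frame(chrom = spec$chrom, start = spec$start, end = spec$end,
               n_haplotypes = spec$n_haplotypes,
               hap_divergence = spec$hap_divergence,
               stringsAsFactors = FALSE))
  truth$karyotypes <- rbind(truth$karyotypes,
    data.frame(sample_id = gm$samples, chrom = spec$chrom,
               hap1 = h1, hap2 = h2,
               karyotype = pair(h1, h2),
               karyotype_main = pair(sw(h1), sw(h2)),
               stringsAsFactors = FALSE))
  truth$sv_haplotypes[[spec$chrom]] <-
    list(pos = pos_new[type != "poly"],
         consensus = H[, type != "poly", drop = FALSE])
  list(gm = gm2, truth = truth)
}

#' Default study-scale simulation configuration
#'
#' Emulates the study conditions at desk scale: 24 chromosomes, 13 of which
#' carry one SV each; three parental lineages with collinear pairwise F_ST
#' targets 0.013 (C-M), 0.075 (C-S), 0.066 (S-M); an admixture gradient with
#' all seven ternary classes represented. The SV haplotype-frequency profiles
#' follow the observed patterns: the southern lineage is `0`-dominant (fixed
#' at 6 of 13 SVs, mean 00 genotype frequency about 77%), the marine lineage
#' is `1`-dominant (mean 11 frequency about 79%), three SVs carry the
#' southern haplotype fixed in the coastal lineage, three segregate three
#' haplotypes (a northern `1a`/`1b` sub-split), and one is polymorphic in all
#' northern groups.
#'
#' @param seed master seed.
#' @param n_chroms,sites_per_chrom,chrom_length_bp genome scale knobs.
#' @return A [sim_config()].
#' @export
default_study_config <- function(seed = 1L, n_chroms = 24,
                                 sites_per_chrom = 5000,
                                 chrom_length_bp = 1e6) {
  chroms <- sprintf("chr%02d", seq_len(n_chroms))
  sc <- chrom_length_bp / 1e6       # SV coordinates scale with the genome
  mk2 <- function(i, f0_C, f0_S, f0_M, div, start, end) {
    sv_spec(chroms[i], round(start * sc), round(end * sc), div,
            c(f0_C, f0_S, f0_M))
  }
  mk3 <- function(i, div, start, end, f_C, f_S, f_M) {
    k <- rbind(C = f_C, S = f_S, M = f_M)
    colnames(k) <- c("0", "1a", "1b")
    sv_spec(chroms[i], round(start * sc), round(end * sc), div, k)
  }
  svs <- list(
    # southern haplotype fixed in the coastal lineage (3 SVs)
    mk2(1, 1.00, 1.00, 0.10, 0.0016, 300000, 450000),
    mk2(2, 1.00, 1.00, 0.10, 0.0015, 250000, 400000),
    mk2(3, 1.00, 1.00, 0.10, 0.0017, 350000, 500000),
    # three segregating haplotypes: northern 1a (coastal) / 1b (marine) split
    mk3(4, 0.0016, 300000, 450000,
        c(0.05, 0.90, 0.05), c(1, 0, 0), c(0.07, 0.08, 0.85)),
    mk3(5, 0.0015, 320000, 470000,
        c(0.05, 0.90, 0.05), c(1, 0, 0), c(0.07, 0.08, 0.85)),
    mk3(6, 0.0017, 280000, 480000,
        c(0.06, 0.88, 0.06), c(0.76, 0.12, 0.12), c(0.08, 0.07, 0.85)),
    # polymorphic in all northern groups
    mk2(7, 0.50, 0.80, 0.15, 0.0016, 300000, 550000),
    # southern-private 0 haplotype; northern groups 1-dominant
    mk2(8, 0.12, 1.00, 0.12, 0.0016, 300000, 450000),
    mk2(9, 0.10, 0.80, 0.10, 0.0016, 260000, 410000),
    mk2(10, 0.10, 0.80, 0.10, 0.0016, 340000, 490000),
    mk2(11, 0.10, 0.80, 0.10, 0.0016, 300000, 450000),
    mk2(12, 0.10, 0.80, 0.10, 0.0016, 280000, 430000),
    mk2(13, 0.10, 0.80, 0.10, 0.0016, 310000, 460000)
  )
  # smaller genomes carry proportionally fewer SVs (13 per 24 chromosomes)
  n_sv <- if (n_chroms >= 24) 13L else max(1L, floor(13 * n_chroms / 24))
  svs <- svs[seq_len(min(n_sv, n_chroms))]
  sim_config(n_per_group = c(C = 30, S = 30, M = 30,
                             CS = 20, SM = 20, MC = 20, MCS = 30),
             n_chroms = n_chroms, sites_per_chrom = sites_per_chrom,
             chrom_length_bp = chrom_length_bp,
             fst_targets = c(CM = 0.013, CS = 0.075, SM = 0.066),
             sv_specs = svs, seed = seed)
}

#' Run a full simulation: collinear genome plus all configured SVs
#'
#' @param config a [sim_config()].
#' @return `list(gm =, truth =, sample_sheet =)`. The sample sheet assigns
#'   habitat by dominant ancestry (coastal for C-dominant samples, marine
#'   otherwise, matching the observed eco-geographic pattern) and a coarse
#'   location code from the ancestry class.
#' @export
simulate_study <- function(config) {
  out <- simulate_collinear(config)
  # apply each SV on its own chromosome's slice to avoid full-matrix copies
  sv_chroms <- unique(vapply(config$sv_specs, `[[`, "", "chrom"))
  pieces <- lapply(config$chroms, function(ch) {
    gm_subset(out$gm, sites = out$gm$sites$chrom == ch)
  })
  names(pieces) <- config$chroms
  truth <- out$truth
  for (spec in config$sv_specs) {
    res <- simulate_sv(pieces[[spec$chrom]], truth, spec)
    pieces[[spec$chrom]] <- res$gm
    truth <- res$truth
  }
  out <- list(
    gm = genotype_matrix(
      do.call(cbind, lapply(pieces, `[[`, "dosage")),
      do.call(rbind, lapply(pieces, function(p)
        p$sites[, c("chrom", "pos", "ref", "alt")])),
      out$gm$samples),
    truth = truth)
  cls <- out$truth$samples$class
  habitat <- ifelse(out$truth$samples$q_C >
                      pmax(out$truth$samples$q_S, out$truth$samples$q_M),
                    "coastal", "marine")
  location <- c(C = "NTH1", M = "NTH2", MC = "NTH2", CS = "MID1",
                MCS = "MID2", SM = "MID3", S = "STH1")[cls]
  sheet <- data.frame(sample_id = out$truth$samples$sample_id,
                      habitat = habitat, location = unname(location),
                      dataset = "WGS", stringsAsFactors = FALSE)
  list(gm = out$gm, truth = out$truth, sample_sheet = sheet)
}

#' Simulate an admixture gradient along a latitude parameter
#'
#' Ancestry proportions are drawn from a Dirichlet distribution whose mean
#' moves, as latitude increases, from a northern coastal/marine mixture
#' towards pure southern ancestry.
#'
#' @param latitudes numeric vector in `[0, 1]`, one value per location
#'   (1 = southernmost).
#' @param n_per_location samples per location.
#' @param concentration Dirichlet concentration (higher = tighter around the
#'   mean).
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `location`, `latitude`, `q_C`,
#'   `q_S`, `q_M`.
#' @export
sim_admixture_gradient <- function(latitudes = seq(0.05, 0.95, length.out = 5),
                                   n_per_location = 40, concentration = 10,
                                   seed = 1L) {
  set.seed(seed)
  out <- list()
  for (g in seq_along(latitudes)) {
    t <- latitudes[g]
    m <- t * c(0, 1, 0) + (1 - t) * c(0.5, 0, 0.5)
    a <- concentration * pmax(m, 0.02)
    gmat <- matrix(stats::rgamma(3 * n_per_location, shape = rep(a, each = n_per_location)),
                   n_per_location, 3)
    q <- gmat / rowSums(gmat)
    out[[g]] <- data.frame(
      sample_id = sprintf("L%02d_%03d", g, seq_len(n_per_location)),
      location = sprintf("L%02d", g), latitude = t,
      q_C = q[, 1], q_S = q[, 2], q_M = q[, 3], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Serialize a truth table to JSON
#'
#' @param truth truth table from [simulate_study()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  out <- list(samples = truth$samples, lineage_F = as.list(truth$lineage_F),
              svs = truth$svs, karyotypes = truth$karyotypes)
  jsonlite::write_json(out, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}
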