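# single-chromosome simulation where the SV dominates the chromosome PCA
sv_chrom_sim <- function(seed, f0 = c(0.5, 0.9, 0.1), span = c(100000, 300000),
                         three = FALSE) {
  kf <- if (three) {
    k <- rbind(C = c(0.05, 0.90, 0.05), S = c(0.9, 0.05, 0.05),
               M = c(0.05, 0.07, 0.88))
    colnames(k) <- c("0", "1a", "1b"); k
  } else f0
  cfg <- sim_config(n_per_group = c(C = 20, S = 20, M = 20, CS = 8, SM = 8,
                                    MC = 8, MCS = 8),
                    n_chroms = 2, sites_per_chrom = 1500,
                    chrom_length_bp = 500000,
                    sv_specs = list(sv_spec("chr01", span[1], span[2],
                                            0.0017, kf)),
                    seed = seed)
  simulate_study(cfg)
}

true_profiles <- function(sim) {
  data.frame(sample_id = sim$truth$samples$sample_id,
             class = sim$truth$samples$class, stringsAsFactors = FALSE)
}

test_that("the SV axis is selected on an SV chromosome, none on collinear", {
  sim <- sv_chrom_sim(21)
  het1 <- individual_het(sim$gm, region = list(chrom = "chr01"))
  ax <- select_sv_axis(chrom_pca(sim$gm, "chr01"), het1)
  expect_equal(ax, 1L)
  het2 <- individual_het(sim$gm, region = list(chrom = "chr02"))
  expect_true(is.na(select_sv_axis(chrom_pca(sim$gm, "chr02"), het2)))
})

test_that("an SV orthogonal to a stronger geographic split lands on PC2", {
  cfg <- sim_config(n_per_group = c(C = 20, S = 20, M = 20, CS = 0, SM = 0,
                                    MC = 0, MCS = 0),
                    n_chroms = 1, sites_per_chrom = 2000,
                    chrom_length_bp = 500000,
                    fst_targets = c(CM = 0.02, CS = 0.35, SM = 0.35),
                    sv_specs = list(sv_spec("chr01", 150000, 250000, 0.0017,
                                            c(0.5, 0.5, 0.5))),
                    seed = 22)
  sim <- simulate_study(cfg)
  het <- individual_het(sim$gm, region = list(chrom = "chr01",
                                              start = 150000, end = 250000))
  pca <- chrom_pca(sim$gm, "chr01")
  ax <- select_sv_axis(pca, het)
  expect_equal(ax, 2L)
})

test_that("karyotype calls recover the simulated truth at high confidence", {
  sim <- sv_chrom_sim(23)
  g <- gm_region(sim$gm, "chr01", 100000, 300000)
  pca <- gm_pca(g, n_axes = 4)
  calls <- genotype_karyotypes(pca, 1)
  calls <- polarize(calls, true_profiles(sim))
  k <- sim$truth$karyotypes
  m <- match(calls$sample_id, k$sample_id)
  ok <- calls$genotype != "unassigned"
  expect_gt(mean(ok), 0.9)
  expect_equal(calls$genotype[ok], k$karyotype_main[m][ok])
  # heterokaryote recall at default separation
  het_true <- k$karyotype_main[m] == "01"
  expect_gte(mean(calls$genotype[het_true] == "01"), 0.95)
})

test_that("samples midway between clusters are left unassigned", {
  set.seed(24)
  scores <- c(rnorm(20, -10, 0.3), rnorm(20, 0, 0.3), rnorm(20, 10, 0.3), -5)
  pca <- list(coords = matrix(scores, ncol = 1,
                              dimnames = list(c(sprintf("s%02d", 1:60),
                                                "mid"), "PC1")))
  calls <- genotype_karyotypes(pca, 1, threshold = 0.90)
  expect_equal(calls$genotype[calls$sample_id == "mid"], "unassigned")
  expect_true(all(calls$genotype[calls$sample_id != "mid"] != "unassigned"))
})

test_that("a degenerate mixture leaves everything unassigned with a warning", {
  pca <- list(coords = matrix(c(rnorm(30), 50), ncol = 1,
                              dimnames = list(sprintf("s%02d", 1:31), "PC1")))
  expect_warning(calls <- genotype_karyotypes(pca, 1), "degenerate")
  expect_true(all(calls$genotype == "unassigned"))
})

test_that("polarization anchors 00 to the southern-rich cluster", {
  calls <- structure(data.frame(
    sample_id = sprintf("s%02d", 1:9),
    genotype = c("00", "00", "00", "01", "01", "11", "11", "11", "11"),
    confidence = 1, axis_used = 1, stringsAsFactors = FALSE),
    class = c("karyotype_calls", "data.frame"))
  prof <- data.frame(sample_id = sprintf("s%02d", 1:9),
                     class = c("M", "M", "M", "MCS", "MCS", "S", "S", "S", "C"))
  out <- polarize(calls, prof)
  expect_true(attr(out, "polarized"))
  # the S-rich cluster (previously 11) is now 00
  expect_equal(out$genotype[6:9], rep("00", 4))
  expect_equal(out$genotype[1:3], rep("11", 4 - 1))
  expect_equal(unname(attr(out, "evidence")["00"]), 3)
  # relabeling the input clusters leaves the polarized output invariant
  flipped <- calls
  flipped$genotype <- c("11", "11", "11", "01", "01", "00", "00", "00", "00")
  out2 <- polarize(flipped, prof)
  expect_equal(out2$genotype, out$genotype)
})

test_that("polarization is flagged inapplicable without southern samples", {
  calls <- structure(data.frame(
    sample_id = c("a", "b", "c"), genotype = c("00", "01", "11"),
    confidence = 1, axis_used = 1, stringsAsFactors = FALSE),
    class = c("karyotype_calls", "data.frame"))
  prof <- data.frame(sample_id = c("a", "b", "c"), class = c("C", "M", "M"))
  out <- polarize(calls, prof)
  expect_false(attr(out, "polarized"))
  expect_equal(out$genotype, calls$genotype)   # labels stable
})

test_that("local PCA distances are symmetric with zero self-distance", {
  sim <- sv_chrom_sim(25)
  field <- local_pca(sim$gm, "chr01", window = 25000, k = 2, min_sites = 20)
  expect_equal(field$dist, t(field$dist))
  expect_true(all(diag(field$dist) == 0))
  expect_equal(nrow(field$mds), nrow(field$windows))
})

test_that("local PCA separates SV windows from the collinear background", {
  sim <- sv_chrom_sim(26)
  field <- local_pca(sim$gm, "chr01", window = 25000, k = 2, min_sites = 20)
  truth_sv <- field$windows$start >= 100000 & field$windows$end <= 300000
  sil <- cluster::silhouette(as.integer(truth_sv) + 1L,
                             stats::dist(field$mds))
  expect_gt(mean(sil[, "sil_width"]), 0)
  member <- local_field_clusters(field)
  expect_gt(mean(member == truth_sv), 0.8)
  # a collinear chromosome shows no comparable cluster structure
  field2 <- local_pca(sim$gm, "chr02", window = 25000, k = 2, min_sites = 20)
  km <- stats::kmeans(field2$mds, 2, nstart = 5)
  sil2 <- cluster::silhouette(km$cluster, stats::dist(field2$mds))
  expect_lt(mean(sil2[, "sil_width"]), mean(sil[, "sil_width"]))
})

test_that("block delimitation bridges small gaps and splits large ones", {
  st <- data.frame(chrom = "chr01", start = 0:39 * 5000, end = 1:40 * 5000,
                   n_sites = 20L, usable = TRUE, partial = FALSE,
                   pi_A = 0, pi_B = 0, dxy = 0, fst = 0.05, flag = "none")
  st$flag[c(5:10, 13, 14)] <- "q95"       # gap of 2 at 11:12 -> one block
  b <- delimit_block(st, gap = 2)
  expect_equal(nrow(b), 1)
  expect_equal(b$start, 4 * 5000)
  expect_equal(b$end, 14 * 5000)
  st2 <- st; st2$flag <- "none"; st2$flag[c(3:6, 20:25)] <- "q95"
  b2 <- delimit_block(st2, gap = 2)       # 13-window gap -> two blocks
  expect_equal(nrow(b2), 2)
  expect_equal(delimit_block(within(st, flag <- "none"))$start, integer(0))
})

test_that("delimited blocks recover simulated breakpoints within one window", {
  sim <- sv_chrom_sim(27, span = c(100000, 300000))
  ids <- function(cl) sim$truth$samples$sample_id[
    sim$truth$samples$class == cl]
  # the fixture's site density is ~3/kb, so use a matching usability bound
  w <- make_windows(sim$gm$sites, 5000, 8,
                    chrom_lengths = c(chr01 = 500000, chr02 = 500000))
  st <- window_stats(sim$gm, ids("S"), ids("M"), w)
  # flags covering the elevated plateau (inter-haplotype F_ST is far above
  # the collinear background)
  st$flag <- ifelse(st$usable & !is.na(st$fst) & st$fst > 0.3, "q95", "none")
  b <- delimit_block(st[st$chrom == "chr01", ], gap = 2)
  expect_equal(nrow(b), 1)
  expect_lte(abs(b$start - 100000), 5000)
  expect_lte(abs(b$end - 300000), 5000)
})

test_that("frequency tables follow the haplotype-frequency identity", {
  calls <- structure(data.frame(
    sample_id = sprintf("s%02d", 1:10),
    genotype = c("00", "00", "01", "11", "unassigned",
                 "00", "01", "01", "11", "11"),
    confidence = 1, axis_used = 1, stringsAsFactors = FALSE),
    class = c("karyotype_calls", "data.frame"))
  prof <- data.frame(sample_id = sprintf("s%02d", 1:10),
                     class = c(rep("S", 5), rep("M", 5)))
  ft <- freq_tables(calls, prof)
  expect_equal(sort(ft$cluster), c("M", "S"))
  s <- ft[ft$cluster == "S", ]
  expect_equal(s$n_called, 4)            # unassigned excluded
  expect_equal(s$f00 + s$f01 + s$f11, 1)
  expect_equal(s$hap0_freq, (2 * 2 + 1) / 8)
  m <- ft[ft$cluster == "M", ]
  expect_equal(m$hap0_freq, (2 * 1 + 2) / 10)
  # an all-00 cluster gives (1, 0, 0)
  calls$genotype <- "00"
  ft2 <- freq_tables(calls, prof)
  expect_true(all(ft2$f00 == 1 & ft2$f01 == 0 & ft2$f11 == 0))
})

test_that("three-haplotype SVs are detected within the derived haplogroup", {
  sim3 <- sv_chrom_sim(28, three = TRUE)
  g <- gm_region(sim3$gm, "chr01", 100000, 300000)
  pca <- gm_pca(g, n_axes = 4)
  calls <- genotype_karyotypes(pca, 1)
  calls <- polarize(calls, true_profiles(sim3))
  scan3 <- third_haplotype_scan(sim3$gm, calls, "chr01",
                                region = list(start = 100000, end = 300000))
  expect_equal(scan3$status, "ok")
  expect_true(scan3$detected)
  # sub-group assignments concordant with the simulated sub-haplotypes
  k <- sim3$truth$karyotypes
  truth_sub <- setNames(k$karyotype, k$sample_id)[names(scan3$subgroup)]
  tab <- table(scan3$subgroup, truth_sub)
  expect_gte(sum(apply(tab, 2, max)) / sum(tab), 0.95)

  sim2 <- sv_chrom_sim(29)               # plain two-haplotype SV
  g2 <- gm_region(sim2$gm, "chr01", 100000, 300000)
  calls2 <- polarize(genotype_karyotypes(gm_pca(g2, n_axes = 4), 1),
                     true_profiles(sim2))
  scan2 <- third_haplotype_scan(sim2$gm, calls2, "chr01",
                                region = list(start = 100000, end = 300000))
  expect_false(scan2$detected)
})

test_that("third-haplotype scan reports insufficient data without 11 calls", {
  calls <- structure(data.frame(sample_id = c("a", "b"),
                                genotype = c("00", "01"),
                                confidence = 1, axis_used = 1,
                                stringsAsFactors = FALSE),
                     class = c("karyotype_calls", "data.frame"))
  gm <- make_gm(matrix(0L, 2, 5), samples = c("a", "b"))
  out <- third_haplotype_scan(gm, calls, "chr01")
  expect_equal(out$status, "insufficient data")
})

test_that("called karyotypes are consistent with Hardy-Weinberg equilibrium", {
  # panmictic population at one SV: called genotype counts pass the exact
  # test in nearly all replicates
  pvals <- vapply(1:20, function(r) {
    f0 <- 0.5
    cfg <- sim_config(n_per_group = c(C = 60, S = 0, M = 0, CS = 0, SM = 0,
                                      MC = 0, MCS = 0),
                      n_chroms = 1, sites_per_chrom = 800,
                      chrom_length_bp = 300000,
                      sv_specs = list(sv_spec("chr01", 50000, 250000, 0.0017,
                                              c(f0, f0, f0))),
                      seed = 400 + r)
    sim <- simulate_study(cfg)
    g <- gm_region(sim$gm, "chr01", 50000, 250000)
    calls <- genotype_karyotypes(gm_pca(g, n_axes = 2), 1)
    n <- table(factor(calls$genotype, levels = c("00", "01", "11")))
    hwe_exact_p(n[["00"]], n[["01"]], n[["11"]])
  }, 0)
  expect_gte(mean(pvals > 0.01), 0.95)
})
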