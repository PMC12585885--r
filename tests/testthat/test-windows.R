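test_that("window tiling matches the BED convention with a partial tail", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 4000L, 11999L))
  w <- make_windows(sites, size = 5000, min_sites = 1,
                    chrom_lengths = c(chr1 = 12000))
  expect_equal(w$start, c(0L, 5000L, 10000L))
  expect_equal(w$end, c(5000L, 10000L, 12000L))
  expect_equal(w$partial, c(FALSE, FALSE, TRUE))
  expect_equal(w$n_sites, c(2L, 0L, 1L))
})

test_that("14 sites fail the 15-site minimum; 15 pass", {
  sites <- data.frame(chrom = "chr1", pos = as.integer(1:14 * 300))
  w <- make_windows(sites, size = 5000, min_sites = 15,
                    chrom_lengths = c(chr1 = 5000))
  expect_false(w$usable[1])
  sites15 <- data.frame(chrom = "chr1", pos = as.integer(1:15 * 300))
  expect_true(make_windows(sites15, 5000, 15,
                           c(chr1 = 5000))$usable[1])
})

test_that("per-window site counts equal brute-force bin counts", {
  set.seed(3)
  pos <- sort(sample.int(50000, 400))
  w <- make_windows(data.frame(chrom = "c", pos = pos), size = 5000,
                    min_sites = 1, chrom_lengths = c(c = 50000))
  brute <- vapply(seq_len(nrow(w)), function(i) {
    sum(pos - 1 >= w$start[i] & pos - 1 < w$end[i])
  }, integer(1))
  expect_equal(w$n_sites, brute)
})

test_that("pi: monomorphic zero, the two-diploid site term, all-pairs oracle", {
  win <- list(chrom = "chr01", start = 0, end = 100)
  expect_equal(pi_window(make_gm(matrix(0L, 4, 3), pos = c(5L, 50L, 90L)),
                         sprintf("s%02d", 1:4), win), 0)
  # dosages {0, 2}: p = 0.5, n = 4 alleles -> 2 * 0.25 * 4/3 = 2/3 per site
  gm1 <- make_gm(matrix(c(0L, 2L), 2, 1), pos = 10L)
  expect_equal(pi_window(gm1, c("s01", "s02"), win) * 100, 2 / 3,
               tolerance = 1e-12)
  set.seed(9)
  dos <- matrix(sample(c(0:2, NA), 6 * 12, TRUE), nrow = 6)
  gm <- make_gm(dos, pos = as.integer(sort(sample.int(99, 12))))
  expect_equal(pi_window(gm, sprintf("s%02d", 1:6), win),
               oracle_pi(dos, 100), tolerance = 1e-10)
})

test_that("dxy: within equals between for one pop, fixed difference, oracle", {
  win <- list(chrom = "chr01", start = 0, end = 5000)
  # same samples in both pops: dxy = sum 2p(1-p)/span over sample freqs
  dos <- matrix(c(0L, 1L, 2L, 1L), 4, 1)
  gm <- make_gm(dos, pos = 100L)
  p <- mean(dos) / 2
  expect_equal(dxy_window(gm, sprintf("s%02d", 1:4), sprintf("s%02d", 1:4),
                          win), 2 * p * (1 - p) / 5000)
  # one fixed difference in a 5 kb window
  gm2 <- make_gm(cbind(c(0L, 0L, 2L, 2L)), pos = 100L)
  expect_equal(dxy_window(gm2, c("s01", "s02"), c("s03", "s04"), win), 2e-4)
  set.seed(10)
  dosA <- matrix(sample(c(0:2, NA), 5 * 20, TRUE), nrow = 5)
  dosB <- matrix(sample(c(0:2, NA), 7 * 20, TRUE), nrow = 7)
  gm3 <- make_gm(rbind(dosA, dosB), pos = as.integer(1:20 * 100))
  expect_equal(
    dxy_window(gm3, sprintf("s%02d", 1:5), sprintf("s%02d", 6:12),
               list(chrom = "chr01", start = 0, end = 2500)),
    oracle_dxy(dosA, dosB, 2500), tolerance = 1e-10)
})

test_that("F_ST: fixed difference gives 1, identical pops near 0, oracle match", {
  win <- list(chrom = "chr01", start = 0, end = 1000)
  gm <- make_gm(rbind(matrix(0L, 5, 8), matrix(2L, 5, 8)),
                pos = as.integer(1:8 * 100))
  a <- sprintf("s%02d", 1:5); b <- sprintf("s%02d", 6:10)
  expect_equal(fst_window(gm, a, b, win, "hudson"), 1)
  expect_equal(fst_window(gm, a, b, win, "wc"), 1)
  set.seed(2)
  dos <- matrix(rbinom(10 * 40, 2, 0.4), nrow = 10)
  gm2 <- make_gm(rbind(dos, dos), pos = as.integer(1:40 * 10))
  # identical genotype sets: estimator is 0 up to its sampling correction
  expect_lt(abs(fst_window(gm2, sprintf("s%02d", 1:10),
                           sprintf("s%02d", 11:20), win, "hudson")), 0.08)
  set.seed(21)
  dosA <- matrix(rbinom(10 * 50, 2, runif(50, 0.1, 0.9)), 10, byrow = TRUE)
  dosB <- matrix(rbinom(10 * 50, 2, runif(50, 0.1, 0.9)), 10, byrow = TRUE)
  gm3 <- make_gm(rbind(dosA, dosB), pos = as.integer(1:50 * 10))
  expect_equal(
    fst_window(gm3, sprintf("s%02d", 1:10), sprintf("s%02d", 11:20), win),
    oracle_hudson(dosA, dosB), tolerance = 1e-10)
})

test_that("Hudson F_ST is invariant to allele-label swap and bounded by 1", {
  set.seed(14)
  for (rep in 1:5) {
    dos <- matrix(rbinom(12 * 30, 2, runif(30, 0.05, 0.95)), 12, byrow = TRUE)
    gm <- make_gm(dos, pos = as.integer(1:30 * 10))
    win <- list(chrom = "chr01", start = 0, end = 300)
    a <- sprintf("s%02d", 1:6); b <- sprintf("s%02d", 7:12)
    f1 <- fst_window(gm, a, b, win)
    gm_sw <- make_gm(2L - dos, pos = as.integer(1:30 * 10))
    expect_equal(fst_window(gm_sw, a, b, win), f1, tolerance = 1e-12)
    expect_lte(f1, 1)
    # permutation of sample order leaves the statistic unchanged
    perm <- sample(12)
    gm_p <- gm_subset(gm, samples = perm)
    expect_equal(fst_window(gm_p, a, b, win), f1, tolerance = 1e-12)
  }
})

test_that("window_stats agrees with the single-window functions", {
  set.seed(8)
  dos <- matrix(sample(c(0:2, NA), 12 * 120, TRUE, c(.4, .3, .25, .05)), 12)
  gm <- make_gm(dos, pos = as.integer(sort(sample.int(20000, 120))))
  a <- sprintf("s%02d", 1:6); b <- sprintf("s%02d", 7:12)
  w <- make_windows(gm$sites, size = 5000, min_sites = 5,
                    chrom_lengths = c(chr01 = 20000))
  st <- window_stats(gm, a, b, w)
  for (i in which(st$usable)) {
    win <- list(chrom = "chr01", start = st$start[i], end = st$end[i])
    expect_equal(st$pi_A[i], pi_window(gm, a, win), tolerance = 1e-12)
    expect_equal(st$dxy[i], dxy_window(gm, a, b, win), tolerance = 1e-12)
    expect_equal(st$fst[i], fst_window(gm, a, b, win), tolerance = 1e-12)
  }
  # d_XY of a population against itself equals its pi on the same samples
  stAA <- window_stats(gm, a, a, w)
  ok <- stAA$usable
  # dxy uses plain sample freqs; pi uses the n/(n-1) correction
  raw_pi <- vapply(which(ok), function(i) {
    g <- gm_region(gm, "chr01", stAA$start[i], stAA$end[i])
    f <- svkaryo:::.site_freq(g, a)
    sum(2 * f$p[f$n >= 1] * (1 - f$p[f$n >= 1])) / (stAA$end[i] - stAA$start[i])
  }, 0)
  expect_equal(stAA$dxy[ok], raw_pi, tolerance = 1e-12)
})

test_that("individual heterozygosity counts het calls over non-missing", {
  dos <- rbind(c(0L, 2L, 0L, 2L, NA),   # all homozygous
               c(1L, 1L, 0L, NA, 1L),   # 3 het of 4 calls
               c(1L, 0L, 1L, 1L, 0L))   # 3 het of 5
  gm <- make_gm(dos)
  h <- individual_het(gm)
  expect_equal(unname(h), c(0, 3 / 4, 3 / 5))
})

test_that("geno_r2: identical vectors 1, null mean near 1/(n-1), LD windows", {
  gm <- make_gm(cbind(c(0L, 1L, 2L, 1L, 0L), c(0L, 1L, 2L, 1L, 0L)))
  expect_equal(geno_r2(gm, 1, 2), 1)
  set.seed(77)
  n <- 25
  r2 <- replicate(400, {
    g <- make_gm(cbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.5)))
    geno_r2(g, 1, 2)
  })
  expect_equal(mean(r2, na.rm = TRUE), 1 / (n - 1), tolerance = 0.2)
  set.seed(78)
  dos <- matrix(rbinom(10 * 100, 2, 0.5), 10)
  gm2 <- make_gm(dos)
  ld <- ld_window_r2(gm2, "chr01", n_snps = 25)
  expect_equal(nrow(ld), 4)
  expect_true(all(ld$mean_r2 >= 0 & ld$mean_r2 <= 1))
})

test_that("quantile flags: 100 distinct windows give exactly 5 q95 and 1 q99", {
  set.seed(1)
  st <- data.frame(chrom = "c", start = 0:99 * 5000, end = 1:100 * 5000,
                   n_sites = 20L, usable = TRUE, partial = FALSE,
                   pi_A = 0, pi_B = 0, dxy = 0,
                   fst = sample(seq(0.01, 1, length.out = 100)),
                   flag = "none")
  fl <- quantile_flags(st)
  expect_equal(sum(fl$flag %in% c("q95", "q99")), 5)
  expect_equal(sum(fl$flag == "q99"), 1)
  # constant landscape: nothing strictly above its own quantile
  st$fst <- 0.3
  expect_equal(sum(quantile_flags(st)$flag != "none"), 0)
})

test_that("flags equal an independent sort-and-threshold oracle", {
  set.seed(33)
  st <- data.frame(chrom = "c", start = 0:199 * 5000, end = 1:200 * 5000,
                   n_sites = 20L, usable = rep(c(TRUE, TRUE, TRUE, FALSE), 50),
                   partial = FALSE, pi_A = 0, pi_B = 0, dxy = 0,
                   fst = rbeta(200, 2, 8), flag = "none")
  fl <- quantile_flags(st)
  x <- st$fst[st$usable]
  t95 <- quantile(x, 0.95, type = 7); t99 <- quantile(x, 0.99, type = 7)
  oracle <- ifelse(st$usable & st$fst > t99, "q99",
                   ifelse(st$usable & st$fst > t95, "q95", "none"))
  expect_equal(fl$flag, unname(oracle))
})

test_that("chromosome rule: exactly 2.5% is not flagged under strict >", {
  st <- data.frame(chrom = rep(c("A", "B"), each = 200),
                   start = rep(0:199 * 5000, 2), end = rep(1:200 * 5000, 2),
                   n_sites = 20L, usable = TRUE, partial = FALSE,
                   pi_A = 0, pi_B = 0, dxy = 0, fst = 0.1,
                   flag = "none")
  st$flag[st$chrom == "A"][1:5] <- "q95"       # exactly 2.5% of 200
  st$flag[st$chrom == "B"][1:6] <- "q95"       # 3%
  out <- chromosome_sv_flag(st)
  expect_equal(out$sv_flag, c(FALSE, TRUE))
  expect_equal(chromosome_sv_flag(st, comparator = ">=")$sv_flag[1], TRUE)
  st$flag <- "q95"
  expect_true(all(chromosome_sv_flag(st)$sv_flag))
})
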