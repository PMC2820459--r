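# Fixture: 6 chromosomes, 7 SNPs at known positions; the focal site is
# column 4.  Derived (1) carriers split into haplotype groups whose EHH
# decays stepwise away from the focal site.
ehh_fixture <- function() {
  X <- rbind(
    c(0, 0, 0, 1, 0, 0, 0),
    c(0, 0, 0, 1, 0, 0, 1),
    c(0, 1, 1, 1, 1, 0, 0),
    c(1, 1, 1, 1, 1, 1, 0),
    c(0, 0, 1, 0, 0, 1, 1),
    c(1, 1, 0, 0, 1, 0, 1))
  make_sample(X, c(100, 200, 300, 400, 500, 600, 700), 800)
}

test_that("EHH equals the expected homozygosity of haplotype frequencies", {
  hs <- ehh_fixture()
  expect_equal(ehh(hs, 1:4, c(350, 450)), 1)          # identical over focal
  expect_equal(ehh(hs, 3:4, c(0, 800)), 0.5)          # two equal haplotypes
  # counts (2,1,1) among 4 carriers
  expect_equal(ehh(hs, 1:4, c(350, 650)), (2/4)^2 + (1/4)^2 + (1/4)^2)
  expect_error(ehh(hs, integer(0), c(0, 800)), "empty")
  # brute-force enumeration agrees on arbitrary carrier sets and intervals
  set.seed(401)
  for (i in 1:20) {
    carriers <- sample(1:6, sample(2:6, 1))
    iv <- sort(runif(2, 0, 800))
    cols <- which(hs$positions >= iv[1] & hs$positions < iv[2])
    expect_equal(ehh(hs, carriers, iv),
                 brute_ehh(hs$alleles, carriers, cols))
  }
})

test_that("EHH is non-increasing as the interval grows", {
  set.seed(402)
  for (rep in 1:10) {
    X <- matrix(rbinom(20 * 15, 1, 0.5), 20, 15)
    hs <- make_sample(X, seq(10, 150, by = 10), 160)
    carriers <- sample(1:20, 10)
    mid <- 80
    vals <- vapply(seq(10, 80, by = 10), function(w)
      ehh(hs, carriers, c(mid - w, mid + w)), numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("iHH matches independent trapezoid integration on the fixture", {
  hs <- ehh_fixture()
  # derived carriers at the focal site: rows 1-4
  carriers <- which(hs$alleles[, 4] == 1)
  dist_r <- c(100, 200, 300)
  ehh_r <- vapply(5:7, function(j)
    brute_ehh(hs$alleles, carriers, 5:j), numeric(1))
  dist_l <- c(100, 200, 300)
  ehh_l <- vapply(3:1, function(j)
    brute_ehh(hs$alleles, carriers, j:3), numeric(1))
  expected <- brute_trapezoid(dist_r, ehh_r) + brute_trapezoid(dist_l, ehh_l)
  got <- ihh(hs, 4, 1)
  expect_equal(got$area, expected)
  expect_true(got$edge_truncated)   # EHH never drops below 0.05 here
})

test_that("iHH integrates a constant EHH of 1 across the reachable span", {
  X <- matrix(1, 6, 3); X[5:6, 2] <- 0
  hs <- make_sample(X, c(0, 5e5, 1e6 - 1), 1e6)
  r <- ihh(hs, 2, 1)
  expect_equal(r$area, 1e6 - 1)
  expect_true(r$edge_truncated)
  # near-degenerate: EHH falls below the cutoff at the SNPs adjacent to the
  # focal site on both sides, leaving only the interpolated sliver
  # (with two haplotype groups the adjacent EHH is 0.5; crossing at 0.6
  # interpolates to 80 bp with trapezoid area 64 per side)
  hs2 <- make_sample(rbind(
    c(0, 1, 0), c(1, 1, 1), c(0, 1, 1), c(1, 1, 0), c(0, 1, 0), c(1, 1, 1)),
    c(100, 200, 300), 400)
  r2 <- ihh(hs2, 2, 1, ehh_cutoff = 0.6)
  expect_equal(r2$area, 2 * (80 * (1 + 0.6) / 2))
  expect_false(r2$edge_truncated)
})

test_that("iHH requires at least two carriers", {
  hs <- ehh_fixture()
  X <- hs$alleles; X[, 4] <- c(1, rep(0, 5))
  hs1 <- make_sample(X, hs$positions, 800)
  expect_error(ihh(hs1, 4, 1), "carriers")
})

test_that("unstandardized iHS is the log ratio and is antisymmetric", {
  set.seed(403)
  X <- matrix(rbinom(30 * 21, 1, 0.5), 30, 21)
  X[, 11] <- rep(c(0, 1), 15)
  hs <- make_sample(X, seq(50, 1050, by = 50), 1100)
  r <- ihs_unstandardized(hs, 11)
  expect_equal(r$value, log(r$ihh_a / r$ihh_d))
  # swapping ancestral/derived labels flips the sign
  hs_flip <- make_sample(cbind(X[, 1:10], 1 - X[, 11], X[, 12:21]),
                         hs$positions, 1100)
  r_flip <- ihs_unstandardized(hs_flip, 11)
  expect_equal(r_flip$value, -r$value)
  # symmetric haplotype structure around both alleles gives zero
  Xs <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1), c(0, 0, 1))
  hss <- make_sample(Xs, c(10, 20, 30), 40)
  expect_equal(ihs_unstandardized(hss, 2)$value, 0)
})

test_that("batched per-site iHS agrees with the single-site route", {
  set.seed(404)
  m <- demographic_model(list(epoch(0, Inf, sizes = 2000)))
  g <- simulate_genealogy(m, NULL, n = 30, region_length = 5e4,
                          recomb_rate = 1e-7)
  hs <- drop_mutations(g, 1e-7)
  sites <- sample(ncol(hs$alleles), 15)
  tab <- ihs_scan(hs, sites)
  for (i in seq_along(sites)) {
    r <- ihs_unstandardized(hs, sites[i])
    if (is.na(r$value)) expect_true(is.na(tab$ihs_raw[i]))
    else expect_equal(tab$ihs_raw[i], r$value)
  }
})

test_that("standardization yields zero mean and unit variance within bins", {
  set.seed(405)
  stats <- data.frame(daf = runif(2000, 0.05, 0.95),
                      ihs_raw = rnorm(2000), edge_both = FALSE)
  stats$ihs_raw <- stats$ihs_raw - 2 * stats$daf   # frequency-dependent mean
  out <- standardize_ihs(stats)
  for (b in unique(out$bin)) {
    v <- out$ihs_std[out$bin == b]
    if (length(v) >= 20) {
      expect_lt(abs(mean(v)), 1e-12)
      expect_equal(sd(v), 1, tolerance = 1e-12)
    }
  }
  # half-open binning: a boundary frequency belongs to the bin it starts
  expect_equal(unique(out$bin[out$daf >= 0.10 & out$daf < 0.15]),
               unique(standardize_ihs(data.frame(
                 daf = 0.10, ihs_raw = 0, edge_both = FALSE),
                 reference = stats)$bin))
  # sparse bins are merged into a populated neighbor
  sp <- rbind(stats, data.frame(daf = 0.999, ihs_raw = 5, edge_both = FALSE))
  out2 <- standardize_ihs(sp)
  expect_false(is.na(out2$ihs_std[nrow(out2)]))
})

test_that("both-edge-truncated sites do not influence the bin estimates", {
  set.seed(407)
  stats <- data.frame(daf = runif(60, 0.28, 0.33),
                      ihs_raw = rnorm(60), edge_both = FALSE)
  extreme <- data.frame(daf = 0.3, ihs_raw = 50, edge_both = TRUE)
  out_clean <- standardize_ihs(stats)
  out_mixed <- standardize_ihs(rbind(stats, extreme))
  # the flagged site still gets a value but the bin parameters are untouched
  expect_equal(out_mixed$ihs_std[1:60], out_clean$ihs_std)
  expect_false(is.na(out_mixed$ihs_std[61]))
  expect_gt(out_mixed$ihs_std[61], 10)
})

test_that("neutral standardized iHS pools to mean 0 and SD 1", {
  set.seed(406)
  m <- demographic_model(list(epoch(0, Inf, sizes = 10000)))
  tabs <- list()
  for (i in 1:16) {
    g <- simulate_genealogy(m, NULL, n = 60, region_length = 4e5,
                            recomb_rate = 1e-8)
    hs <- pair_diploids(apply_ascertainment(drop_mutations(g)))
    maf <- pmin(colMeans(hs$alleles), 1 - colMeans(hs$alleles))
    central <- abs(hs$positions - 2e5) < 1e5
    tabs[[i]] <- ihs_scan(hs, which(maf > 0.05 & central))
  }
  pooled <- do.call(rbind, tabs)
  pooled <- standardize_ihs(pooled)
  z <- pooled$ihs_std[!is.na(pooled$ihs_std)]
  expect_gt(length(z), 5000)
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(sd(z) - 1), 0.05)
})

test_that("LRH compares core-haplotype EHH against the non-core background", {
  # 12 chromosomes; core = 3 SNPs around the focal site; 6 carriers of the
  # major core haplotype stay identical outward while the 6 non-core
  # chromosomes split into two equal haplotype groups (EHH 0.5)
  core <- matrix(rep(c(1, 1, 1), 6), 6, 3, byrow = TRUE)
  noncore <- matrix(rep(c(0, 1, 0), 6), 6, 3, byrow = TRUE)
  out_core <- matrix(1, 6, 4)
  out_non <- rbind(matrix(0, 3, 4), matrix(1, 3, 4))
  X <- rbind(cbind(out_core[, 1:2], core, out_core[, 3:4]),
             cbind(out_non[, 1:2], noncore, out_non[, 3:4]))
  pos <- c(1000, 5000, 9500, 10000, 10500, 15000, 19000)
  hs <- make_sample(X, pos, 20000)
  r <- lrh(hs, 4, core_mode = "span15kb", ehh_decay_cutoff = 0.25,
           core_span = 15000)
  expect_equal(r$ehh_core, 1)
  expect_equal(r$ehh_noncore, 0.5)
  expect_equal(r$ratio, 2)
  expect_equal(r$n_core, 6)
  # cutoff 1.0: evaluation collapses to the core edge
  r0 <- lrh(hs, 4, core_mode = "span15kb", ehh_decay_cutoff = 1.0)
  expect_equal(r0$distance, 0)
  # snp8 core mode resolves and uses at most 8 SNPs
  r8 <- lrh(hs, 4, core_mode = "snp8", ehh_decay_cutoff = 0.25)
  expect_true(is.finite(r8$ratio))
  # all chromosomes sharing one haplotype leaves no non-core background
  hs_mono <- make_sample(matrix(1, 6, 5), c(6000, 8000, 10000, 12000, 14000),
                         20000)
  expect_error(lrh(hs_mono, 3), "core haplotype")
  # core spanning the region edge is an error
  expect_error(lrh(hs, 1, core_mode = "span15kb"), "edge")
})
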