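one_pop <- function(N) demographic_model(list(epoch(0, Inf, sizes = N)))

test_that("zero mutation rate leaves only the selected-site column", {
  set.seed(301)
  m <- one_pop(500)
  pool <- trajectory_pool(m, sweep_parameters(0.1, 60), pool_size = 30)
  tr <- draw_from_pool(pool, 10, 5)
  g <- simulate_genealogy(m, tr, n = 10, x = 5, region_length = 1e4)
  hs <- drop_mutations(g, mu = 0)
  expect_equal(ncol(hs$alleles), 1L)
  expect_equal(hs$selected_site, 1L)
  expect_equal(as.integer(hs$alleles[, 1]), g$sample_class)
})

test_that("segregating sites match Watterson's expectation", {
  set.seed(302)
  N <- 1e4; L <- 1e4; mu <- 2.2e-8; n <- 10
  m <- one_pop(N)
  S <- replicate(800, ncol(drop_mutations(
    simulate_genealogy(m, NULL, n = n, region_length = L,
                       recomb_rate = 1e-8), mu)$alleles))
  expected <- 4 * N * mu * L * sum(1 / seq_len(n - 1))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("every emitted column is polymorphic in the sample", {
  set.seed(303)
  m <- one_pop(2000)
  g <- simulate_genealogy(m, NULL, n = 12, region_length = 5e4,
                          recomb_rate = 1e-8)
  hs <- drop_mutations(g, 1e-7)
  cs <- colSums(hs$alleles)
  expect_true(all(cs >= 1 & cs <= nrow(hs$alleles) - 1))
  expect_false(is.unsorted(hs$positions, strictly = TRUE))
})

test_that("mutation counts are Poisson with the branch-measure mean", {
  set.seed(304)
  # fixed tiny genealogy: 2 samples, one root at time 100, 1 kb
  gen <- structure(list(
    nodes = data.frame(id = 0:2, time = c(0, 0, 100), subpop = 1L),
    edges = data.frame(parent = c(2L, 2L), child = c(0L, 1L),
                       left = 0, right = 1000),
    n_samples = 2L, sample_class = c(0L, 0L), sample_subpop = 1L,
    selected_pos = 500, region_length = 1000),
    class = "sweepsim_genealogy")
  mu <- 2e-6
  lambda <- mu * 1000 * 100 * 2
  counts <- replicate(2000, ncol(drop_mutations(gen, mu)$alleles))
  # chi-square goodness of fit against the Poisson pmf
  br <- 0:max(counts)
  obs <- tabulate(counts + 1, nbins = length(br))
  pr <- dpois(br, lambda); pr[length(pr)] <- 1 - ppois(max(br) - 1, lambda)
  keep <- pr * length(counts) >= 5
  chi <- sum((obs[keep] - length(counts) * pr[keep])^2 /
             (length(counts) * pr[keep]))
  expect_lt(chi, qchisq(0.999, sum(keep) - 1))
})

test_that("ascertainment retains exactly the panel-polymorphic columns", {
  set.seed(305)
  X <- rbind(c(1, 1, 0, 1), c(1, 0, 0, 1), c(0, 0, 1, 1), c(0, 0, 1, 0),
             c(0, 0, 0, 0), c(0, 0, 0, 0))
  hs <- make_sample(X, c(10, 20, 30, 40), 100)
  full <- apply_ascertainment(hs, frac = 1)
  expect_identical(full$alleles, hs$alleles)       # identity at frac = 1
  asc <- apply_ascertainment(hs, frac = 1 / 3)     # panel of 2 chromosomes
  expect_true(all(asc$positions %in% hs$positions))
  kept <- match(asc$positions, hs$positions)
  expect_identical(asc$alleles, hs$alleles[, kept, drop = FALSE])
  # retained columns are polymorphic in some 2-chromosome subset; columns
  # monomorphic across all pairs could never be retained
  expect_error(apply_ascertainment(hs, frac = 0.1), "at least 2")
})

test_that("ascertainment depletes singletons disproportionately", {
  set.seed(306)
  m <- one_pop(5000)
  sing_raw <- 0; tot_raw <- 0; sing_asc <- 0; tot_asc <- 0
  for (i in 1:40) {
    g <- simulate_genealogy(m, NULL, n = 40, region_length = 2e4,
                            recomb_rate = 1e-8)
    hs <- drop_mutations(g, 1e-7)
    cs <- colSums(hs$alleles)
    sing_raw <- sing_raw + sum(cs == 1); tot_raw <- tot_raw + length(cs)
    asc <- apply_ascertainment(hs, frac = 0.2)
    cs2 <- colSums(asc$alleles)
    sing_asc <- sing_asc + sum(cs2 == 1); tot_asc <- tot_asc + length(cs2)
  }
  expect_lt(sing_asc / tot_asc, sing_raw / tot_raw)
})

test_that("the selected site obeys the ascertainment filter unless forced", {
  set.seed(307)
  m <- one_pop(1000)
  pool <- trajectory_pool(m, sweep_parameters(0.1, 80), pool_size = 40)
  forced_kept <- 0
  for (i in 1:10) {
    tr <- draw_from_pool(pool, 20, 2)   # rare favored allele
    g <- simulate_genealogy(m, tr, n = 20, x = 2, region_length = 1e4)
    hs <- drop_mutations(g, 1e-7)
    asc <- apply_ascertainment(hs, frac = 0.15,
                               force_retain_selected = TRUE)
    forced_kept <- forced_kept + !is.na(asc$selected_site)
    if (!is.na(asc$selected_site))
      expect_equal(asc$positions[asc$selected_site], g$selected_pos)
  }
  expect_equal(forced_kept, 10)
})

test_that("diploid pairing is a uniform perfect matching", {
  set.seed(308)
  hs <- make_sample(matrix(0:1, 2, 3), c(1, 2, 3), 10)
  p <- pair_diploids(hs)
  expect_equal(nrow(p$diploid_pairs), 1L)
  expect_setequal(as.vector(p$diploid_pairs), 1:2)
  hs8 <- make_sample(matrix(rbinom(80, 1, 0.5), 8, 10), 1:10, 20)
  p1 <- pair_diploids(hs8)$diploid_pairs
  expect_setequal(as.vector(p1), 1:8)
  expect_true(all(table(as.vector(p1)) == 1))
  # different seeds give different matchings with high probability
  matchings <- vapply(1:5, function(s) {
    set.seed(1000 + s)
    paste(t(pair_diploids(hs8)$diploid_pairs), collapse = ",")
  }, character(1))
  expect_gt(length(unique(matchings)), 1L)
  expect_error(pair_diploids(make_sample(matrix(0, 3, 1), 1, 10)), "even")
})

test_that("ms-style output round-trips", {
  set.seed(309)
  m <- one_pop(1000)
  g <- simulate_genealogy(m, NULL, n = 6, region_length = 1e4,
                          recomb_rate = 1e-8)
  hs <- drop_mutations(g, 1e-7)
  f <- tempfile(fileext = ".ms")
  write_ms(list(hs, hs), f)
  back <- read_ms(f, region_length = 1e4)
  expect_length(back, 2L)
  expect_identical(back[[1]]$alleles, unname(hs$alleles))
  expect_equal(back[[1]]$positions, hs$positions, tolerance = 1e-6)
})

test_that("VCF output round-trips with phased genotypes and AA polarity", {
  skip_if_not_installed("vcfR")
  set.seed(310)
  X <- matrix(rbinom(60, 1, 0.4), 6, 10)
  X <- X[, colSums(X) > 0 & colSums(X) < 6, drop = FALSE]
  pos <- sort(sample(1:1000, ncol(X)))
  hs <- make_sample(X, pos, 2000,
                    pairs = matrix(1:6, ncol = 2, byrow = TRUE))
  f <- tempfile(fileext = ".vcf")
  write_vcf(hs, f)
  back <- read_vcf_haplotypes(f, region_length = 2000)
  expect_identical(unname(back$alleles), unname(hs$alleles))
  expect_equal(back$positions, hs$positions)
})

test_that("unphased or unpolarized VCF records are rejected by name", {
  skip_if_not_installed("vcfR")
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1,length=1000>",
           '##INFO=<ID=AA,Number=1,Type=String,Description="AA">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "ind1", sep = "\t"))
  f1 <- tempfile(fileext = ".vcf")
  writeLines(c(hdr, paste("1", "5", ".", "A", "G", ".", "PASS", "AA=A",
                          "GT", "0/1", sep = "\t")), f1)
  expect_error(read_vcf_haplotypes(f1), "unphased")
  f2 <- tempfile(fileext = ".vcf")
  writeLines(c(hdr, paste("1", "5", ".", "A", "G", ".", "PASS", "DP=3",
                          "GT", "0|1", sep = "\t")), f2)
  expect_error(read_vcf_haplotypes(f2), "AA")
})
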