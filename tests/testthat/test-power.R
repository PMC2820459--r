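# synthetic scan records: per-locus iHS SNP tables and ALnLH deviation
# summaries drawn from simple distributions (no simulation needed to test
# the scan bookkeeping)
fake_records <- function(n_loci, truth, snps = 60, shift = 0, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_loci), function(i) {
    raw <- rnorm(snps) + if (truth == "selected") shift else 0
    # per-allele squared deviations; selected loci have one allele fitting
    # the sweep model (tiny deviations)
    g2_0 <- pmax(1e-8, rnorm(snps, 0.002, 1e-4))^2
    g2_1 <- pmax(1e-8, rnorm(snps,
                             if (truth == "selected") 2e-4 else 0.002,
                             1e-4))^2
    list(ihs = data.frame(site = seq_len(snps),
                          pos = seq(1, 1e5, length.out = snps),
                          daf = runif(snps, 0.1, 0.9),
                          ihh_a = 1, ihh_d = 1,
                          ihs_raw = raw, edge_both = FALSE),
         alnlh = data.frame(site = seq_len(snps),
                            pos = seq(1, 2e5, length.out = snps),
                            daf = runif(snps, 0.1, 0.9), eligible = TRUE,
                            g_sum_0 = sqrt(g2_0) * 40, g2_sum_0 = g2_0 * 40,
                            n_sites_0 = 40L,
                            g_sum_1 = sqrt(g2_1) * 40, g2_sum_1 = g2_1 * 40,
                            n_sites_1 = 40L),
         truth = truth)
  })
}

test_that("empirical critical values are type-7 quantiles with a hard floor", {
  set.seed(601)
  v <- rnorm(1000)
  thr <- neutral_critical_value(v, 0.01, "upper")
  expect_equal(thr, quantile(v, 0.99, names = FALSE))
  expect_equal(sum(v > thr), 10)
  expect_equal(neutral_critical_value(v, 0.5, "upper"), median(v))
  two <- suppressWarnings(neutral_critical_value(v, 0.01, "two_sided"))
  expect_equal(mean(v >= two[1] & v <= two[2]), 0.99, tolerance = 0.005)
  expect_error(neutral_critical_value(rnorm(50), 0.01), "at least")
  expect_warning(neutral_critical_value(rnorm(200), 0.01), "imprecise")
})

test_that("single-site power behaves as a rejection rate", {
  set.seed(602)
  null_vals <- rnorm(5000)
  thr <- neutral_critical_value(rnorm(5000), 0.01, "upper")
  expect_equal(single_site_power(null_vals, thr, "upper"), 0.01,
               tolerance = 0.006)
  expect_equal(single_site_power(rep(thr + 1, 50), thr, "upper"), 1)
  thr05 <- neutral_critical_value(null_vals, 0.05, "upper")
  sel <- rnorm(500, 2)
  expect_gte(single_site_power(sel, thr05, "upper"),
             single_site_power(sel, thr, "upper"))
  expect_equal(single_site_power(c(NA, thr + 1), thr, "upper"), 0.5)
})

test_that("iHS window statistics hit their trivial bounds", {
  rec <- fake_records(30, "neutral", seed = 603)
  # no SNP passes: shrink all raw values to zero spread
  rec0 <- lapply(rec, function(r) { r$ihs$ihs_raw <- 0; r })
  # with zero variance standardization is degenerate; use a mixed set
  rec_mix <- c(rec, fake_records(5, "selected", shift = 30, seed = 604))
  sc <- ihs_window_scan(rec_mix, top_fraction = 0.1)
  w <- sc$windows
  # shifted loci have nearly every SNP beyond |iHS| = 2; neutral loci none
  expect_true(all(w$wstat[w$truth == "selected"] > 0.5))
  expect_true(all(w$wstat[w$truth == "neutral"] <
                  min(w$wstat[w$truth == "selected"])))
  # pure-neutral input: the empirical rule calls the top fraction exactly
  scn <- ihs_window_scan(rec, top_fraction = 0.1)
  expect_equal(sum(scn$windows$candidate), 3, tolerance = 1)
})

test_that("ALnLH gene scan aggregates per-SNP flags and inflates per-gene rates", {
  set.seed(605)
  neutral <- fake_records(400, "neutral", seed = 606)
  gs <- alnlh_gene_scan(neutral)
  snp_rate <- gs$snp_flag_rate
  gene_rate <- mean(gs$genes$candidate)
  expect_gt(snp_rate, 0)
  # multiplicity: testing every SNP in the window inflates the per-gene rate
  expect_gt(gene_rate, snp_rate)
  # no flagged SNPs anywhere -> no candidate genes
  flat <- lapply(neutral, function(r) {
    r$alnlh$g2_sum_0[] <- 0.001; r$alnlh$g2_sum_1[] <- 0.001
    r$alnlh$g_sum_0[] <- sqrt(0.001 * 40); r$alnlh$g_sum_1[] <- sqrt(0.001 * 40)
    r
  })
  # scores identical at every site: nothing reaches mu + 2.6 sd
  gs0 <- alnlh_gene_scan(flat)
  expect_equal(sum(gs0$genes$candidate), 0)
})

test_that("mixture bookkeeping: FDR, FPR and call counts are consistent", {
  pools <- list(neutral = fake_records(150, "neutral", seed = 607),
                selected = fake_records(60, "selected", shift = 6,
                                        seed = 608))
  set.seed(609)
  r <- mixture_experiment(pools, f = 0.02, "ihs_window",
                          genome_loci = 500)
  expect_true(r$power >= 0 && r$power <= 1)
  expect_true(r$false_discovery_rate >= 0 && r$false_discovery_rate <= 1)
  # integer bookkeeping: FDR * calls = false calls exactly
  expect_equal(r$false_discovery_rate * r$n_calls,
               round(r$false_discovery_rate * r$n_calls))
  # f = 0: every call is a false discovery
  r0 <- mixture_experiment(pools, f = 0, "ihs_window", genome_loci = 500)
  if (r0$n_calls > 0) expect_equal(r0$false_discovery_rate, 1)
  expect_gt(r0$power, 0.5)   # power is still measured against the pool
  # f = 1: no neutral loci, FPR undefined
  r1 <- mixture_experiment(pools, f = 1, "ihs_window", genome_loci = 200)
  expect_true(is.na(r1$false_positive_rate))
  expect_error(mixture_experiment(pools, f = -0.1, "ihs_window"), "f must")
})

test_that("FDR falls as the selected fraction of the genome grows", {
  pools <- list(neutral = fake_records(200, "neutral", seed = 610),
                selected = fake_records(80, "selected", shift = 6,
                                        seed = 611))
  set.seed(612)
  fdr <- vapply(c(0.005, 0.08), function(f)
    mean(replicate(5, mixture_experiment(pools, f, "ihs_window",
                                         genome_loci = 800)$false_discovery_rate)),
    numeric(1))
  expect_gt(fdr[1], fdr[2])
})

test_that("frequency-matched neutral focal sites are found near the center", {
  set.seed(613)
  m <- demographic_model(list(epoch(0, Inf, sizes = 10000)))
  hs <- simulate_locus(m, n = 60, region_length = 1e5)
  j <- pick_focal_site(hs, 0.4)
  expect_false(is.na(j))
  expect_lt(abs(mean(hs$alleles[, j]) - 0.4), 0.05 + 1e-12)
  expect_true(abs(hs$positions[j] - 5e4) <= 2.5e4)
  expect_true(is.na(pick_focal_site(hs, 0.4, tol = 0)))
})

test_that("a miniature end-to-end experiment separates sweeps from neutrality", {
  set.seed(614)
  exp <- single_site_experiment(presets = "constant", freqs = 0.6,
                                n = 60, region_length = 3e5,
                                n_neutral = 100, n_selected = 15,
                                pool_size = 100)
  expect_s3_class(exp, "sweepsim_single_site")
  pow <- suppressWarnings(power_from_experiment(exp, level = 0.05))
  p_ihs <- pow$power$power[pow$power$statistic == "ihs"]
  expect_gt(p_ihs, 0.5)
  expect_true(all(pow$power$power >= 0 & pow$power$power <= 1))
})
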