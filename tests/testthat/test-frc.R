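test_that("FRC counts inferred recombinants among evaluation chromosomes", {
  # 4 carriers of the focal allele; perfect LD and a 3:1 split
  X <- rbind(c(1, 0, 1), c(1, 0, 1), c(1, 0, 1), c(1, 0, 0),
             c(0, 1, 0), c(0, 1, 0))
  hs <- make_sample(X, c(10, 20, 30), 40)
  expect_equal(frc(hs, 1, 1, 2), 0)        # perfect LD
  expect_equal(frc(hs, 1, 1, 3), 0.25)     # carriers split 3:1
  # 50/50 tie returns 0.5
  X2 <- rbind(c(1, 1), c(1, 1), c(1, 0), c(1, 0))
  expect_equal(frc(make_sample(X2, c(1, 2), 10), 1, 1, 2), 0.5)
  # relabeling alleles at the other site leaves FRC unchanged
  hs_flip <- make_sample(cbind(X[, 1:2], 1 - X[, 3]), c(10, 20, 30), 40)
  expect_equal(frc(hs_flip, 1, 1, 3), frc(hs, 1, 1, 3))
})

test_that("unphased FRC uses focal-homozygote diploids and errors without them", {
  X <- rbind(c(1, 1), c(1, 1),    # diploid 1: hom favored
             c(0, 0), c(0, 0),    # diploid 2: hom ancestral
             c(0, 1), c(0, 0))    # diploid 3: hom ancestral
  hs <- make_sample(X, c(5, 15), 20,
                    pairs = matrix(1:6, ncol = 2, byrow = TRUE))
  expect_equal(frc(hs, 1, 1, 2, phased = FALSE), 0)   # both chroms carry 1
  expect_equal(frc(hs, 1, 0, 2, phased = FALSE), 0.25)
  X3 <- X; X3[c(1, 3, 5), 1] <- c(1, 1, 1); X3[c(2, 4, 6), 1] <- 0
  hs3 <- make_sample(X3, c(5, 15), 20,
                     pairs = matrix(1:6, ncol = 2, byrow = TRUE))
  expect_error(frc(hs3, 1, 1, 2, phased = FALSE), "homozygous")
})

test_that("the sweep-model sigmoid has the stated shape", {
  p <- sweep_model_params(a = 0.4, x0 = 1e5, b = 3e4)
  expect_equal(sweep_model_F(1e5, p), 0.2)            # midpoint = a/2
  expect_lt(abs(sweep_model_F(1e9, p) - 0.4), 1e-12)  # asymptote
  X <- seq(0, 5e5, by = 1e4)
  expect_true(all(diff(sweep_model_F(X, p)) > 0))     # monotone
  expect_error(sweep_model_params(a = 1.4, x0 = 1, b = 1), "asymptote")
  expect_error(sweep_model_params(a = 0.4, x0 = 1, b = -1), "steepness")
  # packaged defaults load from the bundled synthetic calibration
  d <- sweep_model_params()
  expect_true(d$a > 0 && d$a <= 1 && d$b > 0)
})

test_that("the bundled synthetic decay table matches the packaged fit", {
  tab <- read.table(system.file("extdata", "sweep_frc_decay_synthetic.tsv",
                                package = "sweepsim"),
                    header = TRUE, comment.char = "#")
  refit <- fit_sweep_model(tab)
  d <- sweep_model_params()
  expect_equal(refit$a, d$a, tolerance = 0.01)
  expect_equal(refit$x0, d$x0, tolerance = 0.01)
  expect_equal(refit$b, d$b, tolerance = 0.01)
})

test_that("ALnLH is the band-maximized Gaussian pseudo-likelihood average", {
  # focal site plus one scored site at distance 100 with FRC 0.5
  X <- rbind(c(1, 1), c(1, 1), c(1, 0), c(1, 0),
             c(0, 1), c(0, 1), c(0, 0), c(0, 0))
  hs <- make_sample(X, c(100, 200), 1000)
  curve <- sweep_model_params(a = 0.2, x0 = 500, b = 50)  # F(100) ~ 0
  fx <- sweep_model_F(100, curve)
  g <- 0.5 - (fx + 0.1)
  r <- alnlh(hs, 1, 1, curve, sigma2 = g^2, window = 500,
             site_maf_min = 0.1)
  expect_equal(r$score, -0.5)      # one site with g = sigma
  expect_equal(r$n_sites_used, 1L)
  # within the band the likelihood is held at its maximum (score 0)
  r0 <- alnlh(hs, 1, 1, sweep_model_params(a = 0.5, x0 = 0, b = 1),
              sigma2 = 1, window = 500)
  expect_equal(r0$score, 0)
  # quadrupling sigma^2 scales the score by a quarter
  r4 <- alnlh(hs, 1, 1, curve, sigma2 = 4 * g^2, window = 500)
  expect_equal(r4$score, -0.125)
  # no eligible sites -> undefined, flagged
  rn <- alnlh(hs, 1, 1, curve, sigma2 = 1, window = 50)
  expect_true(is.na(rn$score))
  expect_equal(rn$excluded_reason, "no_eligible_sites")
})

test_that("ALnLH scores are never positive and zero only inside the band", {
  set.seed(501)
  m <- demographic_model(list(epoch(0, Inf, sizes = 5000)))
  g <- simulate_genealogy(m, NULL, n = 40, region_length = 1e5,
                          recomb_rate = 1e-8)
  hs <- drop_mutations(g, 1e-7)
  curve <- sweep_model_params()
  af <- colMeans(hs$alleles)
  sites <- which(pmin(af, 1 - af) > 0.2)[1:5]
  for (j in sites) {
    r <- alnlh(hs, j, 1, curve, sigma2 = 0.01)
    expect_lte(r$score, 0)
    if (r$score == 0) expect_true(all(r$g == 0))
  }
})

test_that("sigma2 is the population variance of pooled deviations", {
  expect_equal(estimate_sigma2(c(0, 0, 1, 1)), 0.25)
  expect_equal(estimate_sigma2(c(0, 2)), 1)
  expect_error(estimate_sigma2(c(1, 1, 1)), "degenerate")
  expect_error(estimate_sigma2(numeric(1)), "at least 2")
})

test_that("the candidate rule applies the 2.6 SD / 1 SD boundaries as stated", {
  mu <- -2; s <- 0.5
  expect_true(alnlh_candidate_rule(mu + 3 * s, mu, mu, s))
  expect_false(alnlh_candidate_rule(mu + 3 * s, mu + 2 * s, mu, s))
  expect_true(alnlh_candidate_rule(mu + 2.6 * s, mu + 0.9 * s, mu, s))
  # boundary: >= 2.6 SD passes, but the other allele must be strictly < 1 SD
  expect_false(alnlh_candidate_rule(mu + 2.6 * s, mu + s, mu, s))
  expect_true(alnlh_candidate_rule(mu, mu + 2.6 * s, mu, s))  # symmetric
})

test_that("bulk scan deviations agree with the single-site route", {
  set.seed(502)
  m <- demographic_model(list(epoch(0, Inf, sizes = 5000)))
  g <- simulate_genealogy(m, NULL, n = 40, region_length = 1e5,
                          recomb_rate = 1e-8)
  hs <- pair_diploids(drop_mutations(g, 1e-7))
  curve <- sweep_model_params()
  for (phased in c(TRUE, FALSE)) {
    bulk <- alnlh_scan_deviations(hs, curve, phased = phased)
    idx <- which(bulk$eligible)[1:8]
    for (f in idx[!is.na(idx)]) {
      for (a in 0:1) {
        dv <- alnlh_deviations(hs, f, a, curve, phased = phased)
        if (dv$n == 0) {
          expect_true(is.na(bulk[[paste0("n_sites_", a)]][f]))
        } else {
          expect_equal(bulk[[paste0("g2_sum_", a)]][f], sum(dv$g^2))
          expect_equal(bulk[[paste0("n_sites_", a)]][f], dv$n)
        }
      }
    }
  }
})

test_that("phased and unphased FRC converge at intermediate frequencies", {
  set.seed(503)
  m <- demographic_model(list(epoch(0, Inf, sizes = 10000)))
  diff_at <- function(target, reps = 12) {
    d <- numeric(0)
    for (i in seq_len(reps)) {
      g <- simulate_genealogy(m, NULL, n = 120, region_length = 1e5,
                              recomb_rate = 1e-8)
      hs <- pair_diploids(drop_mutations(g))
      f <- pick_focal_site(hs, target, tol = 0.04, central = 0.8)
      if (is.na(f)) next
      others <- which(abs(hs$positions - hs$positions[f]) > 0 &
                      pmin(colMeans(hs$alleles),
                           1 - colMeans(hs$alleles)) > 0.1)
      others <- others[seq_len(min(20, length(others)))]
      for (o in others) {
        u <- tryCatch(frc(hs, f, 1, o, phased = FALSE),
                      error = function(e) NA)
        if (!is.na(u)) d <- c(d, abs(frc(hs, f, 1, o) - u))
      }
    }
    mean(d)
  }
  expect_lt(diff_at(0.5), diff_at(0.15))
})
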