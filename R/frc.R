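# ---------------------------------------------------------------------------
# Fraction of recombinant chromosomes (FRC), the sigmoid sweep-model curve,
# and the ALnLH goodness-of-fit statistic with its empirical outlier rule.
# ---------------------------------------------------------------------------

sweep_model_env <- new.env(parent = emptyenv())

#' Sweep-model sigmoid parameters
#'
#' The expected FRC decay away from a swept focal site is modeled as a
#' logistic `F(X) = a / (1 + exp(-(X - x0)/b))` of the distance `X` in bp.
#' The packaged defaults were fitted once to a bundled synthetic FRC decay
#' table (`inst/extdata/sweep_model.yaml`) generated by this package's own
#' simulator under a strong-sweep scenario chosen to resemble the classic
#' G6PD sweep signal; they are configuration values, not estimates from real
#' data.
#'
#' @param a Asymptote (maximum expected FRC, in (0, 1]).
#' @param x0 Midpoint distance in bp (`F(x0) = a/2`).
#' @param b Steepness scale in bp (> 0).
#' @return List of class `sweepsim_sweep_model`.
#' @export
sweep_model_params <- function(a = NULL, x0 = NULL, b = NULL) {
  if (is.null(a) || is.null(x0) || is.null(b)) {
    if (is.null(sweep_model_env$defaults)) {
      path <- system.file("extdata", "sweep_model.yaml", package = "sweepsim",
                          mustWork = TRUE)
      sweep_model_env$defaults <- yaml::read_yaml(path)
    }
    d <- sweep_model_env$defaults
    if (is.null(a)) a <- d$a
    if (is.null(x0)) x0 <- d$x0
    if (is.null(b)) b <- d$b
  }
  if (a <= 0 || a > 1) stop("asymptote a must be in (0, 1]")
  if (b <= 0) stop("steepness b must be > 0")
  structure(list(a = a, x0 = x0, b = b), class = "sweepsim_sweep_model")
}

#' Expected FRC as a function of distance from the focal site
#'
#' @param X Distance(s) from the focal site in bp.
#' @param params A [sweep_model_params()].
#' @return Expected FRC values (same length as `X`).
#' @export
sweep_model_F <- function(X, params = sweep_model_params()) {
  params$a / (1 + exp(-(X - params$x0) / params$b))
}

#' Fit the sweep-model sigmoid to an FRC decay table
#'
#' @param decay Data frame with columns `distance` (bp) and `frc`.
#' @param start Optional start values for the nonlinear fit.
#' @return A [sweep_model_params()].
#' @export
fit_sweep_model <- function(decay, start = list(a = 0.45, x0 = 1e5, b = 5e4)) {
  fit <- nls(frc ~ a / (1 + exp(-(distance - x0) / b)), data = decay,
             start = start)
  p <- as.list(coef(fit))
  sweep_model_params(a = p$a, x0 = p$x0, b = p$b)
}

#' Fraction of recombinant chromosomes between two sites
#'
#' Among the evaluation chromosomes (phased: all carriers of the focal
#' allele; unphased: both chromosomes of every diploid homozygous for the
#' focal allele), identifies the majority allele at `other_site` within the
#' set and returns the fraction carrying the minority allele (the inferred
#' recombinants).  A 50/50 tie returns 0.5.
#'
#' @param sample A `sweepsim_haplotypes` (unphased mode requires
#'   `diploid_pairs`).
#' @param focal_site,other_site Column indices.
#' @param focal_allele Allele (0/1) defining the evaluation set.
#' @param phased Use phased carriers (`TRUE`) or focal-homozygote diploids
#'   (`FALSE`).
#' @return Fraction in `[0, 0.5]`.
#' @export
frc <- function(sample, focal_site, focal_allele, other_site, phased = TRUE) {
  if (phased) {
    ev <- which(sample$alleles[, focal_site] == focal_allele)
    if (length(ev) < 2L)
      stop("fewer than 2 phased carriers of the focal allele")
  } else {
    pairs <- sample$diploid_pairs
    if (is.null(pairs)) stop("unphased FRC requires diploid pairing")
    hom <- sample$alleles[pairs[, 1L], focal_site] == focal_allele &
           sample$alleles[pairs[, 2L], focal_site] == focal_allele
    if (!any(hom)) stop("no diploids homozygous for the focal allele")
    ev <- as.vector(pairs[hom, , drop = FALSE])
  }
  m <- mean(sample$alleles[ev, other_site])
  min(m, 1 - m)
}

#' Population variance of pooled FRC deviations
#'
#' `sigma^2` for the ALnLH likelihood kernel: the population variance of the
#' deviation values `g` pooled over an entire empirical site collection
#' (zeros included).
#'
#' @param g Numeric vector of deviations (length >= 2).
#' @return The population variance.
#' @export
estimate_sigma2 <- function(g) {
  if (length(g) < 2L) stop("need at least 2 deviation values")
  v <- mean((g - mean(g))^2)
  if (v <= 0) stop("degenerate deviation distribution (all values equal)")
  v
}

# per-site FRC deviations from the sweep-model band for one focal allele
alnlh_deviations <- function(sample, focal_site, allele,
                             curve = sweep_model_params(),
                             window = 5e5, site_maf_min = 0.1,
                             phased = TRUE, tol_band = 0.1, af = NULL) {
  pos <- sample$positions
  fp <- pos[focal_site]
  if (is.null(af)) af <- colMeans(sample$alleles)
  maf <- pmin(af, 1 - af)
  elig <- which(abs(pos - fp) <= window & maf > site_maf_min &
                seq_along(pos) != focal_site)
  if (!length(elig))
    return(list(g = numeric(0), n = 0L, reason = "no_eligible_sites"))
  if (phased) {
    ev <- which(sample$alleles[, focal_site] == allele)
    if (length(ev) < 2L)
      return(list(g = numeric(0), n = 0L, reason = "too_few_carriers"))
  } else {
    pairs <- sample$diploid_pairs
    if (is.null(pairs))
      return(list(g = numeric(0), n = 0L, reason = "unpaired"))
    hom <- sample$alleles[pairs[, 1L], focal_site] == allele &
           sample$alleles[pairs[, 2L], focal_site] == allele
    if (!any(hom))
      return(list(g = numeric(0), n = 0L, reason = "no_homozygotes"))
    ev <- as.vector(pairs[hom, , drop = FALSE])
  }
  m <- colMeans(sample$alleles[ev, elig, drop = FALSE])
  Y <- pmin(m, 1 - m)
  X <- abs(pos[elig] - fp)
  band <- sweep_model_F(X, curve) + tol_band
  g <- pmax(0, Y - band)
  list(g = g, n = length(elig), reason = NA_character_)
}

#' ALnLH goodness-of-fit score for one allele at a focal site
#'
#' For every site within `window` of the focal site with minor allele
#' frequency above `site_maf_min`, computes the FRC `Y_i` for the focal
#' allele, its deviation `g_i = max(0, Y_i - (F(X_i) + 0.1))` above the
#' sweep-model tolerance band, the per-site log likelihood
#' `-g_i^2 / (2 sigma^2)` (Gaussian kernel, additive constant dropped, the
#' likelihood held at its maximum inside the band), and returns the average.
#' The score is always <= 0, with 0 attained exactly when every eligible
#' site lies within the band.
#'
#' @inheritParams frc
#' @param allele Focal allele (0/1).
#' @param curve A [sweep_model_params()].
#' @param sigma2 Variance of `g` over the empirical distribution (see
#'   [estimate_sigma2()]).
#' @param window Window half-width in bp (default 500 kb).
#' @param site_maf_min Minor-allele-frequency floor for scored sites
#'   (default 0.1).
#' @param tol_band Band width added to `F(X)` (default 0.1).
#' @return List with `score`, `n_sites_used`, `g` (deviation vector) and
#'   `excluded_reason` (`NA` when defined).
#' @export
alnlh <- function(sample, focal_site, allele, curve = sweep_model_params(),
                  sigma2, window = 5e5, site_maf_min = 0.1, phased = TRUE,
                  tol_band = 0.1) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  dev <- alnlh_deviations(sample, focal_site, allele, curve, window,
                          site_maf_min, phased, tol_band)
  if (dev$n == 0L)
    return(list(score = NA_real_, n_sites_used = 0L, g = numeric(0),
                excluded_reason = dev$reason))
  list(score = -mean(dev$g^2) / (2 * sigma2), n_sites_used = dev$n,
       g = dev$g, excluded_reason = NA_character_)
}

#' Empirical outlier candidate rule for ALnLH
#'
#' A site is a candidate for positive selection when one allele's score is
#' at least 2.6 empirical standard deviations above the empirical mean while
#' the other allele's score is below 1 standard deviation above the mean.
#'
#' @param score1,score2 Scores of the two alleles (vectors).
#' @param mu,sigma Mean and SD of the empirical score distribution.
#' @return Logical vector of candidate flags (`NA` where either score is
#'   missing).
#' @export
alnlh_candidate_rule <- function(score1, score2, mu, sigma) {
  hi1 <- score1 >= mu + 2.6 * sigma
  hi2 <- score2 >= mu + 2.6 * sigma
  lo1 <- score1 < mu + sigma
  lo2 <- score2 < mu + sigma
  (hi1 & lo2) | (hi2 & lo1)
}

# ---------------------------------------------------------------------------
# Bulk per-site ALnLH deviations for genome scans (matrix cross-products)
# ---------------------------------------------------------------------------

#' Per-site ALnLH deviation summaries for all eligible focal sites
#'
#' Computes, for every eligible focal site and both alleles, the FRC
#' deviations against the sweep-model band over all scored sites in the
#' window, returning the deviation sums needed to score the scan (the score
#' of allele `a` is `-(g2_sum_a / n_sites_a) / (2 sigma^2)`).
#' Focal-site eligibility: for unphased scans, the frequency of diploids
#' homozygous for the minor allele must exceed `hom_maf_min`; for phased
#' scans, the minor allele frequency must exceed `hom_maf_min`.
#'
#' @inheritParams alnlh
#' @param hom_maf_min Focal eligibility threshold (default 0.05).
#' @return Data frame: `site`, `pos`, `daf`, `eligible`, and per allele
#'   `g_sum_*`, `g2_sum_*`, `n_sites_*`.
#' @export
alnlh_scan_deviations <- function(sample, curve = sweep_model_params(),
                                  phased = FALSE, window = 5e5,
                                  site_maf_min = 0.1, hom_maf_min = 0.05,
                                  tol_band = 0.1) {
  X <- sample$alleles
  n <- nrow(X); S <- ncol(X)
  pos <- sample$positions
  af <- colMeans(X)
  maf <- pmin(af, 1 - af)
  scored <- maf > site_maf_min

  if (phased) {
    eligible <- maf > hom_maf_min
    c1 <- colSums(X)
    cpf <- crossprod(X)   # S x S co-occurrence counts of allele 1
  } else {
    pairs <- sample$diploid_pairs
    if (is.null(pairs)) stop("unphased scan requires diploid pairing")
    G <- X[pairs[, 1L], , drop = FALSE] + X[pairs[, 2L], , drop = FALSE]
    H1 <- G == 2L
    H0 <- G == 0L
    nh1 <- colSums(H1); nh0 <- colSums(H0)
    D <- nrow(G)
    eligible <- pmin(nh0, nh1) / D > hom_maf_min
    cp1 <- crossprod(H1, G)   # S x S: allele-1 copies at k among hom1 at f
    cp0 <- crossprod(H0, G)
  }

  out <- data.frame(site = seq_len(S), pos = pos, daf = af,
                    eligible = eligible,
                    g_sum_0 = NA_real_, g2_sum_0 = NA_real_,
                    n_sites_0 = NA_integer_,
                    g_sum_1 = NA_real_, g2_sum_1 = NA_real_,
                    n_sites_1 = NA_integer_)
  band_of <- function(Xd) sweep_model_F(Xd, curve) + tol_band
  for (f in which(eligible)) {
    k <- which(scored & abs(pos - pos[f]) <= window & seq_len(S) != f)
    if (!length(k)) next
    Xd <- abs(pos[k] - pos[f])
    band <- band_of(Xd)
    for (a in 0:1) {
      if (phased) {
        ne <- if (a == 1L) c1[f] else n - c1[f]
        if (ne < 2L) next
        n11 <- cpf[k, f]
        cnt <- if (a == 1L) n11 else c1[k] - n11
        m <- cnt / ne
      } else {
        nh <- if (a == 1L) nh1[f] else nh0[f]
        if (nh < 1L) next
        cnt <- if (a == 1L) cp1[f, k] else cp0[f, k]
        m <- cnt / (2 * nh)
      }
      Y <- pmin(m, 1 - m)
      g <- pmax(0, Y - band)
      out[[paste0("g_sum_", a)]][f] <- sum(g)
      out[[paste0("g2_sum_", a)]][f] <- sum(g^2)
      out[[paste0("n_sites_", a)]][f] <- length(k)
    }
  }
  out
}
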