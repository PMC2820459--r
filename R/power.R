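# ---------------------------------------------------------------------------
# Single-site power analysis against neutral critical values, genome-scan
# emulation (window-aggregated iHS; per-SNP ALnLH with gene-level
# aggregation), and power / false-positive-rate / false-discovery-rate
# computation under neutral-selected mixtures.
# ---------------------------------------------------------------------------

#' Empirical critical value from neutral statistics
#'
#' @param values Neutral focal-site statistic values (NAs dropped).
#' @param level Significance level (default 0.01).
#' @param tail `"upper"`, `"lower"` or `"two_sided"` (the latter returns a
#'   symmetric pair of thresholds at `level/2` per side).
#' @return Threshold (length 2 for two-sided).
#' @export
neutral_critical_value <- function(values, level = 0.01,
                                   tail = c("upper", "lower", "two_sided")) {
  tail <- match.arg(tail)
  values <- values[!is.na(values)]
  if (length(values) < 1 / level)
    stop("need at least ", ceiling(1 / level),
         " neutral replicates for level ", level)
  if (length(values) < 5 / level)
    warning("fewer than ", ceiling(5 / level), " neutral replicates; the ",
            "critical value at level ", level, " is imprecise")
  switch(tail,
         upper = quantile(values, 1 - level, names = FALSE, type = 7),
         lower = quantile(values, level, names = FALSE, type = 7),
         two_sided = c(quantile(values, level / 2, names = FALSE, type = 7),
                       quantile(values, 1 - level / 2, names = FALSE,
                                type = 7)))
}

#' Single-site power against a critical value
#'
#' @param values Selected-replicate focal-site statistics (NAs count as not
#'   significant).
#' @param threshold Critical value(s) from [neutral_critical_value()].
#' @param tail Tail of the test.
#' @return Fraction of replicates beyond the threshold.
#' @export
single_site_power <- function(values, threshold,
                              tail = c("upper", "lower", "two_sided")) {
  tail <- match.arg(tail)
  hit <- switch(tail,
                upper = values > threshold,
                lower = values < threshold,
                two_sided = values < threshold[1] | values > threshold[2])
  hit[is.na(hit)] <- FALSE
  mean(hit)
}

# ---------------------------------------------------------------------------
# Single-site experiment driver
# ---------------------------------------------------------------------------

# focal-site statistics for one replicate: raw iHS plus ALnLH deviation
# summaries for both alleles, phased and unphased
focal_site_stats <- function(hs, focal, curve, include_lrh = FALSE,
                             af = NULL) {
  if (is.null(af)) af <- colMeans(hs$alleles)
  row <- list(daf = af[focal])
  r <- ihs_unstandardized(hs, focal)
  row$ihs_raw <- r$value
  row$edge_both <- isTRUE(r$edge_both)
  for (ph in c("p", "u")) {
    for (a in 0:1) {
      dv <- alnlh_deviations(hs, focal, a, curve, phased = ph == "p",
                             af = af)
      row[[paste0("a", ph, "_g_", a)]] <-
        if (dv$n > 0) sum(dv$g) else NA_real_
      row[[paste0("a", ph, "_g2_", a)]] <-
        if (dv$n > 0) sum(dv$g^2) else NA_real_
      row[[paste0("a", ph, "_n_", a)]] <-
        if (dv$n > 0) dv$n else NA_integer_
    }
  }
  if (include_lrh) {
    row$lrh <- tryCatch(lrh(hs, focal)$ratio, error = function(e) NA_real_)
  }
  row
}

#' Run a single-site power experiment
#'
#' For each demographic preset, simulates neutral replicates and, per target
#' favored-allele frequency, selected replicates conditioned on the matching
#' sample count; records raw focal-site statistics.  Neutral replicates are
#' evaluated at frequency-matched focal SNPs (see [pick_focal_site()]).
#' Thresholds and power are computed afterwards with
#' [power_from_experiment()].
#'
#' @param presets Demographic preset names.
#' @param freqs Target favored-allele frequencies.
#' @param n Sample size in chromosomes.
#' @param region_length Region length in bp.
#' @param s Selection coefficient.
#' @param n_neutral Neutral replicates per demography.
#' @param n_selected Selected replicates per (demography, frequency).
#' @param variable_recomb Draw each replicate's recombination rate from an
#'   exponential with mean `mean_recomb` (neutral calibration uses the same
#'   regime).
#' @param mean_recomb Mean recombination rate per bp per generation.
#' @param mu Mutation rate per bp per generation.
#' @param pool_size Trajectory pool size per demography.
#' @param curve Sweep-model curve for ALnLH.
#' @param include_lrh Also record the LRH ratio at focal sites.
#' @param verbose Print progress.
#' @return Object of class `sweepsim_single_site` with the per-replicate
#'   table `loci` and the experiment parameters.
#' @export
single_site_experiment <- function(
    presets = c("constant", "expansion", "expansion_migration",
                "bottleneck_migration"),
    freqs = c(0.2, 0.4, 0.6, 0.8), n = 120L, region_length = 4e5,
    s = 0.022, n_neutral = 500L, n_selected = 50L,
    variable_recomb = FALSE, mean_recomb = 1e-8, mu = 2.2e-8,
    pool_size = 300L, curve = sweep_model_params(), include_lrh = FALSE,
    verbose = FALSE) {
  rows <- list()
  for (preset in presets) {
    model <- build_preset(preset)
    defaults <- attr(model, "sweep_defaults")
    t_org <- defaults$origin_gen
    sw <- sweep_parameters(s = s, origin_gen = t_org,
                           origin_subpop = model$sample_subpop)
    pool <- trajectory_pool(model, sw, pool_size = pool_size)
    if (verbose)
      message(preset, ": trajectory pool built (", pool$n_simulated,
              " forward runs)")
    for (i in seq_len(n_neutral)) {
      rate <- draw_recomb_rate(mean_recomb, variable_recomb)
      hs <- simulate_locus(model, NULL, n = n,
                           region_length = region_length,
                           recomb_rate = rate, mu = mu)
      af <- colMeans(hs$alleles)
      for (f in freqs) {
        focal <- pick_focal_site(hs, f)
        if (is.na(focal)) next
        st <- focal_site_stats(hs, focal, curve, include_lrh, af = af)
        rows[[length(rows) + 1L]] <-
          c(list(demography = preset, truth = "neutral", rep = i,
                 target_freq = f), st)
      }
    }
    for (f in freqs) {
      x <- round(f * n)
      for (i in seq_len(n_selected)) {
        hs <- simulate_locus(model, pool, n = n, x = x,
                             region_length = region_length,
                             recomb_rate = draw_recomb_rate(mean_recomb,
                                                            variable_recomb),
                             mu = mu, force_retain_selected = TRUE)
        if (is.na(hs$selected_site)) next
        st <- focal_site_stats(hs, hs$selected_site, curve, include_lrh)
        rows[[length(rows) + 1L]] <-
          c(list(demography = preset, truth = "selected", rep = i,
                 target_freq = f), st)
      }
      if (verbose) message(preset, " freq ", f, ": selected done")
    }
  }
  loci <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  structure(list(loci = loci,
                 params = list(presets = presets, freqs = freqs, n = n,
                               region_length = region_length, s = s,
                               n_neutral = n_neutral,
                               n_selected = n_selected,
                               variable_recomb = variable_recomb,
                               mean_recomb = mean_recomb, mu = mu)),
            class = "sweepsim_single_site")
}

# ALnLH score statistic (max over the two alleles) from deviation sums
alnlh_stat_from_sums <- function(df, prefix, sigma2) {
  s0 <- -(df[[paste0(prefix, "_g2_0")]] / df[[paste0(prefix, "_n_0")]]) /
    (2 * sigma2)
  s1 <- -(df[[paste0(prefix, "_g2_1")]] / df[[paste0(prefix, "_n_1")]]) /
    (2 * sigma2)
  pmax(s0, s1, na.rm = TRUE)
}

# pooled population variance of the deviations g from per-replicate sums
pooled_sigma2 <- function(df, prefix) {
  gs <- c(df[[paste0(prefix, "_g_0")]], df[[paste0(prefix, "_g_1")]])
  g2 <- c(df[[paste0(prefix, "_g2_0")]], df[[paste0(prefix, "_g2_1")]])
  nn <- c(df[[paste0(prefix, "_n_0")]], df[[paste0(prefix, "_n_1")]])
  ok <- !is.na(nn) & nn > 0
  N <- sum(nn[ok])
  v <- sum(g2[ok]) / N - (sum(gs[ok]) / N)^2
  if (!is.finite(v) || v <= 0)
    stop("degenerate pooled deviation distribution")
  v
}

#' Thresholds and power from a single-site experiment
#'
#' Standardizes iHS within derived-frequency bins against the pooled neutral
#' replicates of each demography, scores ALnLH with the pooled neutral
#' deviation variance, derives per-condition empirical critical values from
#' the neutral replicates, and computes per-condition and average power.
#' Test statistics: `|iHS standardized|` (upper tail) and the larger of the
#' two alleles' ALnLH scores (upper tail), phased and unphased.
#'
#' @param exp A `sweepsim_single_site` experiment.
#' @param level Significance level (default 0.01).
#' @param statistics Statistics to evaluate.
#' @return List with `power` (per demography x frequency x statistic),
#'   `average` (per statistic), `thresholds` and `sigma2`.
#' @export
power_from_experiment <- function(exp, level = 0.01,
                                  statistics = c("ihs", "alnlh_p",
                                                 "alnlh_u")) {
  loci <- exp$loci
  out_pow <- list(); out_thr <- list(); sig <- list()
  for (dem in unique(loci$demography)) {
    dl <- loci[loci$demography == dem, ]
    neut <- dl[dl$truth == "neutral", ]
    # iHS standardization against the pooled neutral reference
    dl <- standardize_ihs(dl, reference = neut)
    dl$stat_ihs <- abs(dl$ihs_std)
    if ("alnlh_p" %in% statistics) {
      s2p <- pooled_sigma2(neut, "ap")
      dl$stat_alnlh_p <- alnlh_stat_from_sums(dl, "ap", s2p)
      sig[[paste0(dem, "_p")]] <- s2p
    }
    if ("alnlh_u" %in% statistics) {
      s2u <- pooled_sigma2(neut, "au")
      dl$stat_alnlh_u <- alnlh_stat_from_sums(dl, "au", s2u)
      sig[[paste0(dem, "_u")]] <- s2u
    }
    if ("lrh" %in% statistics) dl$stat_lrh <- dl$lrh
    for (f in unique(dl$target_freq)) {
      for (stat in statistics) {
        col <- paste0("stat_", stat)
        nv <- dl[[col]][dl$truth == "neutral" & dl$target_freq == f]
        sv <- dl[[col]][dl$truth == "selected" & dl$target_freq == f]
        if (!length(sv)) next
        thr <- neutral_critical_value(nv, level, "upper")
        out_thr[[length(out_thr) + 1L]] <-
          data.frame(demography = dem, target_freq = f, statistic = stat,
                     threshold = thr, n_neutral = sum(!is.na(nv)))
        out_pow[[length(out_pow) + 1L]] <-
          data.frame(demography = dem, target_freq = f, statistic = stat,
                     power = single_site_power(sv, thr, "upper"),
                     n_selected = length(sv))
      }
    }
  }
  power <- do.call(rbind, out_pow)
  avg <- tapply(power$power, power$statistic, mean)
  list(power = power, average = avg,
       thresholds = do.call(rbind, out_thr), sigma2 = sig, level = level)
}

# ---------------------------------------------------------------------------
# Genome-scan records and mixture experiments
# ---------------------------------------------------------------------------

#' Per-locus records for genome-scan emulation
#'
#' Computes, for one simulated locus, the per-SNP raw iHS table inside the
#' central `ihs_window_bp` window and the per-SNP ALnLH deviation summaries
#' (unphased) for focal sites inside the central `gene_window_bp` window.
#'
#' @param hs A `sweepsim_haplotypes` from [simulate_locus()].
#' @param curve Sweep-model curve.
#' @param ihs_window_bp iHS aggregation window (default 100 kb).
#' @param gene_window_bp ALnLH gene window (default 200 kb).
#' @return List with data frames `ihs` and `alnlh` plus `truth`.
#' @export
locus_scan_record <- function(hs, curve = sweep_model_params(),
                              ihs_window_bp = 1e5, gene_window_bp = 2e5) {
  L <- hs$region_length
  ctr <- L / 2
  ihs_sites <- which(abs(hs$positions - ctr) <= ihs_window_bp / 2)
  ihs_tab <- ihs_scan(hs, ihs_sites)
  al <- alnlh_scan_deviations(hs, curve, phased = FALSE)
  al <- al[al$eligible & abs(al$pos - ctr) <= gene_window_bp / 2, ]
  list(ihs = ihs_tab, alnlh = al, truth = attr(hs, "truth"))
}

#' Simulate locus pools for genome-scan mixtures
#'
#' Simulates neutral and selected loci (equal mix of the target frequencies)
#' under the given presets with per-locus exponential recombination rates,
#' and reduces each to its scan record.  The default presets combine an
#' expanding (African-role) and a bottlenecked (European-role) population.
#'
#' @inheritParams single_site_experiment
#' @param n_neutral,n_selected Loci per preset.
#' @return List with `neutral` and `selected` lists of scan records.
#' @export
scan_pools <- function(presets = c("expansion", "bottleneck_migration"),
                       freqs = c(0.2, 0.4, 0.6, 0.8), n = 120L,
                       region_length = 4e5, s = 0.022,
                       n_neutral = 150L, n_selected = 60L,
                       variable_recomb = TRUE, mean_recomb = 1e-8,
                       mu = 2.2e-8, pool_size = 300L,
                       curve = sweep_model_params(), verbose = FALSE) {
  neutral <- list(); selected <- list()
  for (preset in presets) {
    model <- build_preset(preset)
    defaults <- attr(model, "sweep_defaults")
    sw <- sweep_parameters(s = s, origin_gen = defaults$origin_gen,
                           origin_subpop = model$sample_subpop)
    pool <- trajectory_pool(model, sw, pool_size = pool_size)
    for (i in seq_len(n_neutral)) {
      hs <- simulate_locus(model, NULL, n = n,
                           region_length = region_length,
                           recomb_rate = draw_recomb_rate(mean_recomb,
                                                          variable_recomb),
                           mu = mu)
      neutral[[length(neutral) + 1L]] <- locus_scan_record(hs, curve)
    }
    for (i in seq_len(n_selected)) {
      f <- freqs[1L + (i - 1L) %% length(freqs)]
      hs <- simulate_locus(model, pool, n = n, x = round(f * n),
                           region_length = region_length,
                           recomb_rate = draw_recomb_rate(mean_recomb,
                                                          variable_recomb),
                           mu = mu, force_retain_selected = TRUE)
      selected[[length(selected) + 1L]] <- locus_scan_record(hs, curve)
    }
    if (verbose) message(preset, ": scan pool done")
  }
  list(neutral = neutral, selected = selected)
}

# bind scan records into genome tables with locus ids
bind_records <- function(records, what) {
  tabs <- lapply(seq_along(records), function(i) {
    t <- records[[i]][[what]]
    if (!nrow(t)) return(NULL)
    t$locus <- i
    t$truth <- records[[i]]$truth
    t
  })
  do.call(rbind, tabs)
}

#' Window-aggregated iHS scan
#'
#' Standardizes iHS over the pooled SNPs of the supplied loci, computes per
#' locus the fraction of window SNPs with `|iHS|` above
#' `ihs_abs_threshold`, and flags as candidates the windows in the top
#' `top_fraction` of the empirical window-statistic distribution.
#'
#' @param records List of [locus_scan_record()]s (one 100 kb window per
#'   locus, centered on the focal site).
#' @param ihs_abs_threshold Per-SNP |iHS| cutoff (default 2.0).
#' @param top_fraction Candidate fraction of the empirical distribution.
#' @param reference Optional records list providing the standardization and
#'   threshold reference (e.g. a composed pseudo-genome); defaults to
#'   `records`.
#' @return List with per-locus data frame `windows` (`locus`, `truth`,
#'   `wstat`, `candidate`), the `threshold`, and `snp_reference` bins.
#' @export
ihs_window_scan <- function(records, ihs_abs_threshold = 2.0,
                            top_fraction = 0.01, reference = records) {
  snps <- bind_records(records, "ihs")
  ref_snps <- if (identical(reference, records)) snps
              else bind_records(reference, "ihs")
  snps <- standardize_ihs(snps, reference = ref_snps)
  w <- tapply(abs(snps$ihs_std) > ihs_abs_threshold, snps$locus,
              mean, na.rm = TRUE)
  truth <- vapply(records, function(r) r$truth, character(1))
  wstat <- rep(NA_real_, length(records))
  wstat[as.integer(names(w))] <- as.numeric(w)
  # windows with no usable SNPs are excluded
  usable <- !is.na(wstat)
  ref_w <- if (identical(reference, records)) wstat[usable] else {
    rsn <- standardize_ihs(ref_snps, reference = ref_snps)
    rw <- tapply(abs(rsn$ihs_std) > ihs_abs_threshold, rsn$locus, mean,
                 na.rm = TRUE)
    as.numeric(rw)[!is.na(rw)]
  }
  threshold <- quantile(ref_w, 1 - top_fraction, names = FALSE, type = 7)
  data.frame(locus = seq_along(records), truth = truth, wstat = wstat,
             usable = usable,
             candidate = usable & wstat >= threshold) -> windows
  list(windows = windows, threshold = threshold)
}

#' Per-SNP ALnLH scan with gene-level aggregation
#'
#' Scores every eligible SNP (both alleles) with the pooled deviation
#' variance and applies the empirical outlier rule: one allele's score must
#' exceed a high threshold while the other stays below 1 SD above the
#' empirical mean.  In the original formulation the high threshold is 2.6 SD
#' above the mean, which on the originating score distribution flagged the
#' top 1.6% of SNPs; because the shape of the score distribution depends on
#' the data, the scan calibrates the high threshold on the reference
#' distribution so that the flagged fraction matches `top_fraction`
#' (`calibrate = FALSE` keeps the literal 2.6 SD threshold).  Focal sites
#' whose both alleles sit 1 SD above the mean are pre-filtered (the
#' local-recombination control), and a locus (gene) is a candidate when any
#' SNP in its window is flagged.
#'
#' @param records List of [locus_scan_record()]s.
#' @param reference Optional records list for the empirical distribution
#'   (mean, SD, sigma2, calibrated threshold); defaults to `records`.
#' @param local_ld_filter Apply the local-recombination pre-filter.
#' @param top_fraction Target per-SNP flagged fraction (default 0.016).
#' @param calibrate Calibrate the high threshold to `top_fraction` on the
#'   reference distribution.
#' @return List with `genes` (per-locus `locus`, `truth`, `candidate`,
#'   `n_flagged`), `snp_flag_rate`, `params` (`sigma2`, `mu`, `sd`, `hi`).
#' @export
alnlh_gene_scan <- function(records, reference = records,
                            local_ld_filter = TRUE, top_fraction = 0.016,
                            calibrate = TRUE) {
  sites <- bind_records(records, "alnlh")
  ref <- if (identical(reference, records)) sites
         else bind_records(reference, "alnlh")
  # pooled deviation variance over the reference collection
  gs <- c(ref$g_sum_0, ref$g_sum_1); g2 <- c(ref$g2_sum_0, ref$g2_sum_1)
  nn <- c(ref$n_sites_0, ref$n_sites_1)
  ok <- !is.na(nn) & nn > 0
  N <- sum(nn[ok])
  sigma2 <- sum(g2[ok]) / N - (sum(gs[ok]) / N)^2
  score <- function(d) cbind(-(d$g2_sum_0 / d$n_sites_0) / (2 * sigma2),
                             -(d$g2_sum_1 / d$n_sites_1) / (2 * sigma2))
  ref_sc <- score(ref)
  mu <- mean(ref_sc, na.rm = TRUE)
  sdv <- sd(as.numeric(ref_sc), na.rm = TRUE)
  if (local_ld_filter) {
    both_hi <- ref_sc[, 1] >= mu + sdv & ref_sc[, 2] >= mu + sdv
    both_hi[is.na(both_hi)] <- FALSE
    if (any(both_hi)) {
      keep <- as.numeric(ref_sc[!both_hi, ])
      mu <- mean(keep, na.rm = TRUE)
      sdv <- sd(keep, na.rm = TRUE)
    }
  }
  lo <- mu + sdv
  rule_flags <- function(s, hi) {
    fl <- ((s[, 1] >= hi) & (s[, 2] < lo)) | ((s[, 2] >= hi) & (s[, 1] < lo))
    fl[is.na(fl)] <- FALSE
    if (local_ld_filter) {
      bh <- s[, 1] >= lo & s[, 2] >= lo
      bh[is.na(bh)] <- FALSE
      fl <- fl & !bh
    }
    fl
  }
  hi <- mu + 2.6 * sdv
  if (calibrate) {
    # choose the high threshold whose flagged fraction on the reference
    # distribution is closest to top_fraction
    cand_hi <- unique(quantile(as.numeric(ref_sc),
                               probs = seq(0.8, 1 - top_fraction / 4,
                                           length.out = 60),
                               na.rm = TRUE, names = FALSE))
    rates <- vapply(cand_hi, function(h) mean(rule_flags(ref_sc, h)),
                    numeric(1))
    hi <- cand_hi[which.min(abs(rates - top_fraction))]
  }
  sc <- score(sites)
  flag <- rule_flags(sc, hi)
  nf <- tapply(flag, sites$locus, sum)
  truth <- vapply(records, function(r) r$truth, character(1))
  n_flagged <- integer(length(records))
  n_flagged[as.integer(names(nf))] <- as.integer(nf)
  list(genes = data.frame(locus = seq_along(records), truth = truth,
                          n_flagged = n_flagged,
                          candidate = n_flagged > 0L),
       snp_flag_rate = mean(flag),
       params = list(sigma2 = sigma2, mu = mu, sd = sdv, hi = hi))
}

#' Mixture experiment: power, FPR and FDR of an empirical genome scan
#'
#' Composes a pseudo-genome of `genome_loci` loci in which a fraction `f`
#' are selected (sampled with replacement from the pools), derives the scan's
#' empirical thresholds from the mixed distribution (as the original
#' genome scans did), and reports: power (probability a selected locus from
#' the pool is called under those thresholds), the false positive rate
#' (neutral genome loci called / neutral genome loci) and the false
#' discovery rate (false calls / all calls in the genome, `0/0 = 0`).
#'
#' @param pools A [scan_pools()] result.
#' @param f Fraction of the genome influenced by selection, in `[0, 1]`.
#' @param scan `"ihs_window"` or `"alnlh_gene"`.
#' @param genome_loci Number of loci in the composed pseudo-genome.
#' @param top_fraction Candidate fraction for the iHS window scan.
#' @return A `MixtureSummary`-style list: `f`, `scan`, `power`,
#'   `false_positive_rate` (`NA` when `f = 1`), `false_discovery_rate`,
#'   `threshold`, `n_calls`, `genome_loci`, and for the ALnLH scan
#'   `snp_flag_rate`.
#' @export
mixture_experiment <- function(pools, f, scan = c("ihs_window",
                                                  "alnlh_gene"),
                               genome_loci = 1000L, top_fraction = 0.01) {
  scan <- match.arg(scan)
  if (f < 0 || f > 1) stop("f must be in [0, 1]")
  if (!length(pools$neutral) || (!length(pools$selected) && f > 0))
    stop("empty locus pools")
  n_sel <- round(f * genome_loci)
  n_neut <- genome_loci - n_sel
  genome <- c(
    if (n_neut > 0) pools$neutral[sample.int(length(pools$neutral), n_neut,
                                             replace = TRUE)],
    if (n_sel > 0) pools$selected[sample.int(length(pools$selected), n_sel,
                                             replace = TRUE)])
  if (scan == "ihs_window") {
    gw <- ihs_window_scan(genome, top_fraction = top_fraction)
    calls <- gw$windows$candidate
    truth <- gw$windows$truth
    pw <- ihs_window_scan(pools$selected, top_fraction = top_fraction,
                          reference = genome)
    power <- mean(pw$windows$candidate)
    threshold <- gw$threshold
    extra <- list()
  } else {
    gs <- alnlh_gene_scan(genome)
    calls <- gs$genes$candidate
    truth <- gs$genes$truth
    ps <- alnlh_gene_scan(pools$selected, reference = genome)
    power <- mean(ps$genes$candidate)
    threshold <- gs$params$hi
    extra <- list(snp_flag_rate = gs$snp_flag_rate)
  }
  fp <- sum(calls & truth == "neutral")
  n_calls <- sum(calls)
  c(list(f = f, scan = scan, power = power,
         false_positive_rate = if (n_neut > 0)
           fp / sum(truth == "neutral") else NA_real_,
         false_discovery_rate = if (n_calls > 0) fp / n_calls else 0,
         threshold = threshold, n_calls = n_calls,
         genome_loci = genome_loci), extra)
}
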