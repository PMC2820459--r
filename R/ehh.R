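# ---------------------------------------------------------------------------
# Extended haplotype homozygosity statistics: EHH, iHH, iHS (with
# frequency-conditional standardization) and the long-range haplotype test.
#
# EHH is measured as the expected homozygosity given the haplotype
# frequencies (sum of squared frequencies), not the n/(n-1)-corrected sample
# homozygosity.
# ---------------------------------------------------------------------------

#' Extended haplotype homozygosity over an interval
#'
#' Partitions the carrier set by identical allele vectors over the SNPs in
#' `interval` and returns the expected homozygosity `sum(p_k^2)` of the
#' haplotype frequencies within the carrier set.
#'
#' @param sample A `sweepsim_haplotypes`.
#' @param carrier_set Chromosome indices (1-based).
#' @param interval Length-2 bp span `[lo, hi)`.
#' @return EHH in `[0, 1]`.
#' @export
ehh <- function(sample, carrier_set, interval) {
  if (!length(carrier_set)) stop("empty carrier set")
  cols <- which(sample$positions >= interval[1] &
                sample$positions < interval[2])
  if (!length(cols)) return(1.0)
  key <- apply(sample$alleles[carrier_set, cols, drop = FALSE], 1L,
               paste, collapse = "")
  p <- table(key) / length(carrier_set)
  sum(p^2)
}

# outward EHH decay from a focal site among a carrier set; returns the
# per-SNP decay curve for one direction
ehh_decay <- function(sample, focal_site, carrier_set, cutoff, direction) {
  .ehh_walk_cpp(sample$alleles, sample$positions, focal_site - 1L,
                as.integer(carrier_set) - 1L, cutoff, direction)
}

# trapezoid integral of one direction's decay against bp distance from the
# focal position, truncated by interpolation at the cutoff crossing
integrate_decay <- function(walk, focal_pos, cutoff) {
  x <- abs(walk$pos - focal_pos)
  e <- walk$ehh
  if (!length(e)) return(list(area = 0, edge = TRUE))
  x <- c(0, x); e <- c(1, e)
  m <- length(e)
  if (!walk$edge_truncated) {
    # last point is below the cutoff: integrate to the crossing
    x1 <- x[m - 1L]; e1 <- e[m - 1L]; x2 <- x[m]; e2 <- e[m]
    xc <- x1 + (e1 - cutoff) / (e1 - e2) * (x2 - x1)
    x[m] <- xc; e[m] <- cutoff
  }
  area <- sum(diff(x) * (head(e, -1L) + tail(e, -1L)) / 2)
  list(area = area, edge = walk$edge_truncated)
}

#' Integrated EHH (iHH) for one allele at a focal site
#'
#' Walks SNP-by-SNP outward in each direction from the focal site among the
#' carriers of `allele`, evaluating EHH on the growing interval, and
#' integrates the decay (trapezoid rule, the focal site at distance 0 with
#' EHH 1) until EHH first drops below `ehh_cutoff` (linear interpolation to
#' the crossing point).  If EHH never falls below the cutoff before the last
#' SNP, integration stops there and the value is flagged edge-truncated.
#'
#' @inheritParams ehh
#' @param focal_site Column index of the focal site.
#' @param allele Focal allele (0 or 1).
#' @param ehh_cutoff Decay cutoff (default 0.05).
#' @return List with `area` (bp units), `edge_truncated` flag, and carrier
#'   count `n_carriers`.
#' @export
ihh <- function(sample, focal_site, allele, ehh_cutoff = 0.05) {
  carriers <- which(sample$alleles[, focal_site] == allele)
  if (length(carriers) < 2L)
    stop("fewer than 2 carriers of allele ", allele, " at the focal site")
  fp <- sample$positions[focal_site]
  l <- integrate_decay(ehh_decay(sample, focal_site, carriers, ehh_cutoff, -1L),
                       fp, ehh_cutoff)
  r <- integrate_decay(ehh_decay(sample, focal_site, carriers, ehh_cutoff, 1L),
                       fp, ehh_cutoff)
  list(area = l$area + r$area, edge_truncated = l$edge || r$edge,
       n_carriers = length(carriers))
}

#' Unstandardized iHS at a focal site
#'
#' `ln(iHH_ancestral / iHH_derived)`; alleles are polarized with 0 =
#' ancestral.
#'
#' @inheritParams ihh
#' @return List with `value`, `ihh_a`, `ihh_d`, `edge_a`, `edge_d`,
#'   `edge_both` and `daf` (derived allele frequency); `value` is `NA` with
#'   a `reason` when either allele has fewer than 2 carriers or zero iHH.
#' @export
ihs_unstandardized <- function(sample, focal_site, ehh_cutoff = 0.05) {
  col <- sample$alleles[, focal_site]
  n <- length(col)
  nd <- sum(col == 1L)
  daf <- nd / n
  if (nd < 2L || (n - nd) < 2L)
    return(list(value = NA_real_, daf = daf, reason = "carriers"))
  a <- ihh(sample, focal_site, 0L, ehh_cutoff)
  d <- ihh(sample, focal_site, 1L, ehh_cutoff)
  if (a$area <= 0 || d$area <= 0)
    return(list(value = NA_real_, daf = daf, reason = "zero_ihh",
                ihh_a = a$area, ihh_d = d$area))
  list(value = log(a$area / d$area), ihh_a = a$area, ihh_d = d$area,
       edge_a = a$edge_truncated, edge_d = d$edge_truncated,
       edge_both = a$edge_truncated && d$edge_truncated, daf = daf,
       reason = NA_character_)
}

#' Per-site iHS table for a set of sites
#'
#' @inheritParams ihh
#' @param sites Column indices (default: all sites).
#' @return Data frame: `site`, `pos`, `daf`, `ihh_a`, `ihh_d`, `ihs_raw`,
#'   `edge_both`.
#' @export
ihs_scan <- function(sample, sites = seq_len(ncol(sample$alleles)),
                     ehh_cutoff = 0.05) {
  b <- .ihs_batch_cpp(sample$alleles, sample$positions,
                      as.integer(sites) - 1L, ehh_cutoff)
  data.frame(site = sites, pos = sample$positions[sites], daf = b$daf,
             ihh_a = b$ihh_a, ihh_d = b$ihh_d, ihs_raw = b$ihs_raw,
             edge_both = b$edge_both & !is.na(b$ihs_raw))
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Z-transforms raw iHS values using the empirical mean and standard
#' deviation of sites in the same derived-frequency bin (half-open bins
#' `[lo, hi)` of width `bin_width`).  Bins with fewer than `min_bin_count`
#' sites are merged with their nearest neighbor.  Sites that are
#' edge-truncated for both alleles are excluded from the estimation of the
#' bin means/SDs (unbounded haplotypes would otherwise bias the bins) but
#' still receive a standardized value, which stays flagged via `edge_both`.
#'
#' @param stats Data frame from [ihs_scan()] (columns `daf`, `ihs_raw`,
#'   `edge_both`).
#' @param bin_width Derived-frequency bin width (default 0.05).
#' @param min_bin_count Minimum sites per bin before merging (default 20).
#' @param reference Optional data frame with the same columns used to
#'   estimate the bin means/SDs (e.g. pooled neutral simulations); defaults
#'   to `stats` itself.
#' @return `stats` with columns `ihs_std` and `bin` added.
#' @export
standardize_ihs <- function(stats, bin_width = 0.05, min_bin_count = 20L,
                            reference = stats) {
  breaks <- seq(0, 1 + bin_width, by = bin_width)
  bin_of <- function(daf) pmin(findInterval(daf, breaks), length(breaks) - 1L)
  ref_ok <- !is.na(reference$ihs_raw) & !reference$edge_both
  if (!any(ref_ok)) {
    warning("no edge-clean reference sites; estimating bins from all sites")
    ref_ok <- !is.na(reference$ihs_raw)
  }
  rb <- bin_of(reference$daf[ref_ok])
  rv <- reference$ihs_raw[ref_ok]
  cnt <- tabulate(rb, nbins = length(breaks) - 1L)
  # merge sparse bins into their nearest populated neighbor; if no bin is
  # adequately populated, fall back to one global bin
  merged <- seq_along(cnt)
  populated <- which(cnt >= min_bin_count)
  if (!length(populated)) {
    merged[] <- 0L
  } else {
    for (b in seq_along(cnt))
      if (cnt[b] > 0 && cnt[b] < min_bin_count)
        merged[b] <- populated[which.min(abs(populated - b))]
  }
  rb <- merged[rb]
  mu <- tapply(rv, rb, mean)
  sg <- tapply(rv, rb, sd)
  stats$bin <- merged[bin_of(stats$daf)]
  key <- as.character(stats$bin)
  stats$ihs_std <- (stats$ihs_raw - as.numeric(mu[key])) /
    as.numeric(sg[key])
  stats$ihs_std[is.na(stats$ihs_raw)] <- NA_real_
  stats
}

# ---------------------------------------------------------------------------
# Long-range haplotype test
# ---------------------------------------------------------------------------

#' Long-range haplotype (LRH) statistic at a focal site
#'
#' Defines a core haplotype region (a fixed 15 kb span surrounding the focal
#' site, or the 8 SNPs nearest the focal site with minor allele frequency
#' above 0.05 including the focal site), takes the most frequent haplotype
#' over the core as the core haplotype, grows the evaluated interval outward
#' (two-sided, SNPs ordered by distance from the nearer core edge) to the
#' furthest distance at which the core-carrier EHH still exceeds
#' `ehh_decay_cutoff`, and returns `EHH(core carriers) / EHH(non-core
#' carriers)` at that distance.  The default parameters (15 kb core,
#' cutoff 0.25) are the best-performing of the settings examined.
#'
#' @inheritParams ihh
#' @param core_mode `"span15kb"` or `"snp8"`.
#' @param ehh_decay_cutoff EHH level defining the evaluation distance
#'   (default 0.25).
#' @param core_span Core span in bp for `"span15kb"` (default 15000).
#' @return List with `ratio`, `distance` (bp from the focal site of the
#'   furthest SNP used), `ehh_core`, `ehh_noncore`, `n_core`.
#' @export
lrh <- function(sample, focal_site, core_mode = c("span15kb", "snp8"),
                ehh_decay_cutoff = 0.25, core_span = 15000) {
  core_mode <- match.arg(core_mode)
  pos <- sample$positions
  fp <- pos[focal_site]
  n <- nrow(sample$alleles)
  if (core_mode == "span15kb") {
    lo <- fp - core_span / 2; hi <- fp + core_span / 2
    if (lo < 0 || hi > sample$region_length)
      stop("core region spans the region edge")
    core_cols <- which(pos >= lo & pos < hi)
  } else {
    maf <- pmin(colMeans(sample$alleles), 1 - colMeans(sample$alleles))
    elig <- which(maf > 0.05 | seq_along(pos) == focal_site)
    core_cols <- elig[order(abs(pos[elig] - fp))][seq_len(min(8L,
                                                              length(elig)))]
    core_cols <- sort(core_cols)
  }
  key <- apply(sample$alleles[, core_cols, drop = FALSE], 1L, paste,
               collapse = "")
  tab <- sort(table(key), decreasing = TRUE)
  core_hap <- names(tab)[1L]
  core <- which(key == core_hap)
  noncore <- setdiff(seq_len(n), core)
  if (!length(noncore))
    stop("all chromosomes carry the core haplotype; LRH undefined")
  # grow outward over non-core SNPs ordered by distance from the core edge
  core_lo <- min(pos[core_cols]); core_hi <- max(pos[core_cols])
  outside <- which(pos < core_lo | pos > core_hi)
  dist_edge <- pmax(core_lo - pos[outside], pos[outside] - core_hi)
  ord <- outside[order(dist_edge)]
  exp_hom <- function(idx, cols) {
    kk <- apply(sample$alleles[idx, cols, drop = FALSE], 1L, paste,
                collapse = "")
    p <- table(kk) / length(idx)
    sum(p^2)
  }
  best_cols <- core_cols
  best_i <- 0L
  for (i in seq_along(ord)) {
    cols <- sort(c(core_cols, ord[seq_len(i)]))
    if (exp_hom(core, cols) > ehh_decay_cutoff) {
      best_cols <- cols; best_i <- i
    } else break
  }
  e_core <- exp_hom(core, best_cols)
  e_non <- exp_hom(noncore, best_cols)
  if (e_non <= 0) stop("non-core EHH is zero; LRH undefined")
  list(ratio = e_core / e_non,
       distance = if (best_i > 0L) max(abs(pos[setdiff(best_cols,
                                                       core_cols)] - fp))
                  else 0,
       ehh_core = e_core, ehh_noncore = e_non, n_core = length(core))
}
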