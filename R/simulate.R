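# ---------------------------------------------------------------------------
# One-replicate pipeline: trajectory (optional) -> genealogy -> mutations ->
# ascertainment -> diploid pairing.
# ---------------------------------------------------------------------------

#' Simulate one locus end to end
#'
#' Runs the full per-replicate pipeline: an optional conditioned trajectory
#' draw, the structured coalescent with recombination, infinite-sites
#' mutation, discovery-panel ascertainment and random diploid pairing.
#'
#' @param model A [demographic_model()].
#' @param pool A `sweepsim_trajectory_pool` for selected loci, or `NULL` for
#'   a neutral locus.
#' @param n Sample size in chromosomes.
#' @param x Favored-allele count in the sample (ignored for neutral loci).
#' @param region_length Region length in bp.
#' @param recomb_rate Recombination rate per bp per generation for this
#'   locus (see [draw_recomb_rate()]).
#' @param mu Mutation rate per bp per generation.
#' @param ascertain_range Range the discovery-panel fraction is drawn from
#'   uniformly (`NULL` to skip ascertainment).
#' @param force_retain_selected Keep the selected site through ascertainment.
#' @param sample_subpop Sampled subpopulation.
#' @return A `sweepsim_haplotypes` with attributes `truth`
#'   (`"neutral"`/`"selected"`), `recomb_rate` and `target_x`.
#' @export
simulate_locus <- function(model, pool = NULL, n = 120L, x = 0L,
                           region_length = 4e5, recomb_rate = 1e-8,
                           mu = 2.2e-8, ascertain_range = c(0.13, 0.33),
                           force_retain_selected = FALSE,
                           sample_subpop = model$sample_subpop) {
  traj <- NULL
  if (!is.null(pool)) {
    traj <- draw_from_pool(pool, n, x, sample_subpop)
  } else {
    x <- 0L
  }
  g <- simulate_genealogy(model, traj, n = n, x = x,
                          region_length = region_length,
                          recomb_rate = recomb_rate,
                          sample_subpop = sample_subpop)
  hs <- drop_mutations(g, mu)
  if (!is.null(ascertain_range)) {
    # the discovery panel needs at least 2 chromosomes; clamp for tiny n
    frac <- max(runif(1, ascertain_range[1], ascertain_range[2]), 2 / n)
    hs <- apply_ascertainment(hs, frac,
                              force_retain_selected = force_retain_selected)
  }
  hs <- pair_diploids(hs)
  attr(hs, "truth") <- if (is.null(pool)) "neutral" else "selected"
  attr(hs, "recomb_rate") <- recomb_rate
  attr(hs, "target_x") <- x
  hs
}

#' Pick a neutral focal site matched to a target derived frequency
#'
#' Neutral replicates have no designated site; single-site testing evaluates
#' the statistic at the SNP whose derived allele frequency is closest to the
#' selected condition's target frequency, restricted to the central part of
#' the region (mirroring the selected site at the midpoint).
#'
#' @param sample A `sweepsim_haplotypes`.
#' @param target_freq Target derived allele frequency.
#' @param tol Maximum |derived frequency - target|.
#' @param central Fraction of the region (centered) focal sites may occupy.
#' @return Column index, or `NA` if no site qualifies.
#' @export
pick_focal_site <- function(sample, target_freq, tol = 0.05, central = 0.5) {
  pos <- sample$positions
  L <- sample$region_length
  daf <- colMeans(sample$alleles)
  lo <- L * (1 - central) / 2; hi <- L - lo
  ok <- pos >= lo & pos <= hi & abs(daf - target_freq) <= tol
  if (!any(ok)) return(NA_integer_)
  cand <- which(ok)
  cand[order(abs(daf[cand] - target_freq),
             abs(pos[cand] - L / 2))][1L]
}
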