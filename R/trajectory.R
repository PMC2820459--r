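# ---------------------------------------------------------------------------
# Forward Wright-Fisher simulation of a favored allele under genic selection,
# drift and migration, with importance sampling conditioned on the modern
# sample count of the favored allele.
#
# One forward generation step (parents at generation g+1 -> offspring at g):
#   1. selection: p* = p (1 + s) / (1 + p s)   (genic / multiplicative)
#   2. each offspring copy in subpop j draws its source subpopulation from
#      the forward migration matrix (resident with the complementary
#      probability) and is a favored copy with probability p*_source.
# This realizes drift and migration jointly, keeps every 2N_j exact, and
# records the realized per-class migrant counts the backward-time structured
# coalescent conditions on.
# ---------------------------------------------------------------------------

#' Selection parameters for a sweep
#'
#' @param s Selection coefficient (genic/multiplicative fitness), >= 0.
#' @param origin_gen Generation (before present) at which the favored allele
#'   arose as a single copy; >= 1.
#' @param origin_subpop Subpopulation index of the origin.
#' @param fitness_model Currently only `"genic"` (multiplicative) selection,
#'   p* = p(1+s)/(1+ps).
#' @return A list of class `sweepsim_sweep`.
#' @export
sweep_parameters <- function(s = 0.022, origin_gen, origin_subpop = 1L,
                             fitness_model = "genic") {
  if (s < 0) stop("s must be >= 0")
  if (origin_gen < 1) stop("origin_gen must be >= 1")
  fitness_model <- match.arg(fitness_model, "genic")
  structure(list(s = s, origin_gen = as.integer(origin_gen),
                 origin_subpop = as.integer(origin_subpop),
                 fitness_model = fitness_model),
            class = "sweepsim_sweep")
}

# deterministic selection update of the favored-allele frequency
selection_update <- function(p, s) p * (1 + s) / (1 + p * s)

# per-generation size (copies) and migration tables for forward simulation,
# computed once per (model, origin generation) and reused across runs
forward_tables <- function(model, t_org) {
  k <- model$n_subpops
  sizes2N <- matrix(0, t_org + 1L, k)
  for (d in seq_len(k)) sizes2N[, d] <- 2 * size_at(model, d, 0:t_org)
  mig <- lapply(0:t_org, function(g) migration_at(model, g))
  src_prob <- lapply(mig, function(m) {
    sp <- m
    diag(sp) <- 1 - colSums(m)
    sp   # column j = source distribution for offspring in subpop j
  })
  list(sizes2N = sizes2N, src_prob = src_prob, k = k, t_org = t_org)
}

#' Simulate one forward allele trajectory
#'
#' Runs the favored allele forward from a single copy at
#' `sweep$origin_gen` generations before present until it is lost, or until
#' generation 0.  Fixation before generation 0 is retained (such trajectories
#' are legal but receive importance weight 0 when conditioning on a
#' polymorphic sample count); loss is a normal outcome reported by flag, not
#' an error.
#'
#' @param model A [demographic_model()].
#' @param sweep A [sweep_parameters()] object.
#' @param record_migrants Keep per-generation realized migrant counts per
#'   allelic class (required for conditioning a coalescent simulation on the
#'   trajectory).
#' @param tables Precomputed per-generation size/migration tables (internal
#'   reuse across runs; built automatically when `NULL`).
#' @return An object of class `sweepsim_trajectory`, or `NULL` if the allele
#'   was lost.  Fields: `counts` (matrix
#'   `(t+1) x k`, row `g+1` = favored copies at generation `g`), `sizes`
#'   (total allele copies `2N`), `mig_fav`/`mig_neut` (arrays `k x k x t`;
#'   slice `g+1` holds realized copies moving source -> destination while
#'   forming generation `g`), `final_freqs`, and outcome flags.
#' @export
simulate_forward <- function(model, sweep, record_migrants = TRUE,
                             tables = NULL) {
  k <- model$n_subpops
  t_org <- sweep$origin_gen
  s <- sweep$s
  if (sweep$origin_subpop < 1L || sweep$origin_subpop > k)
    stop("origin_subpop out of range")
  if (is.null(tables) || tables$t_org != t_org)
    tables <- forward_tables(model, t_org)
  sizes2N <- tables$sizes2N           # row g+1 = generation g, copies
  counts <- matrix(0L, t_org + 1L, k)
  counts[t_org + 1L, sweep$origin_subpop] <- 1L

  keep_mig <- record_migrants && k > 1L
  if (keep_mig) {
    mig_fav <- array(0, c(k, k, t_org))
    mig_neut <- array(0, c(k, k, t_org))
  }

  for (g in seq(t_org - 1L, 0L)) {
    p <- counts[g + 2L, ] / sizes2N[g + 2L, ]
    pstar <- selection_update(p, s)
    sp <- tables$src_prob[[g + 1L]]
    new_cnt <- integer(k)
    if (k == 1L) {
      new_cnt <- rbinom(1L, sizes2N[g + 1L, 1L], pstar)
    } else {
      for (j in seq_len(k)) {
        slots <- as.vector(rmultinom(1L, sizes2N[g + 1L, j], sp[, j]))
        fav <- rbinom(k, slots, pstar)
        new_cnt[j] <- sum(fav)
        if (keep_mig) {
          fav[j] <- 0
          mig_fav[, j, g + 1L] <- fav
          neut <- slots - fav
          neut[j] <- 0
          mig_neut[, j, g + 1L] <- neut
        }
      }
    }
    counts[g + 1L, ] <- new_cnt
    if (all(new_cnt == 0L)) return(NULL)   # lost: a normal outcome
  }

  structure(list(
    s = s, origin_gen = t_org, origin_subpop = sweep$origin_subpop,
    n_subpops = k, counts = counts, sizes = sizes2N,
    mig_fav = if (keep_mig) mig_fav, mig_neut = if (keep_mig) mig_neut,
    final_freqs = counts[1L, ] / sizes2N[1L, ],
    fixed = all(counts[1L, ] == sizes2N[1L, ]),
    weight = NA_real_), class = "sweepsim_trajectory")
}

#' Importance weight of a trajectory for an observed sample count
#'
#' The weight is the binomial likelihood of drawing `x` favored copies in a
#' sample of `n` chromosomes given the trajectory's final-generation favored
#' frequency in the sampled subpopulation: `choose(n, x) p^x (1-p)^(n-x)`.
#' Because Wright-Fisher drift is Markov, the weight depends only on that
#' final frequency.
#'
#' @param traj A `sweepsim_trajectory`.
#' @param n Sample size in chromosomes.
#' @param x Required favored copies in the sample (0 <= x <= n).
#' @param sample_subpop Sampled subpopulation index.
#' @return Weight in `[0, 1] * choose(n, x)`.
#' @export
importance_weight <- function(traj, n, x,
                              sample_subpop = traj$origin_subpop) {
  if (x < 0 || x > n) stop("x must satisfy 0 <= x <= n")
  p <- traj$final_freqs[sample_subpop]
  if (is.na(p)) stop("undefined sampled subpopulation")
  dbinom(x, n, p)
}

#' Build a pool of surviving forward trajectories
#'
#' Repeats [simulate_forward()] until `pool_size` trajectories that survive
#' (segregating or fixed) to generation 0 have been collected.
#'
#' @inheritParams simulate_forward
#' @param pool_size Number of surviving trajectories to collect.
#' @param max_sims Budget on total forward simulations; exceeding it raises
#'   an error reporting the survival statistics observed so far (some
#'   parameter combinations require a prohibitive number of forward runs).
#' @return List of class `sweepsim_trajectory_pool` with elements
#'   `trajectories`, `n_simulated`, `n_surviving`.
#' @export
trajectory_pool <- function(model, sweep, pool_size = 1000L,
                            max_sims = pool_size * 5000L,
                            record_migrants = TRUE) {
  if (pool_size < 1L) stop("pool_size must be >= 1")
  tables <- forward_tables(model, sweep$origin_gen)
  pool <- vector("list", pool_size)
  got <- 0L; sims <- 0L
  while (got < pool_size) {
    if (sims >= max_sims)
      stop("forward-simulation budget exhausted: ", sims, " runs yielded ",
           got, " surviving trajectories (survival rate ",
           signif(got / sims, 3), "); increase max_sims or reconsider the ",
           "selection/demography parameters")
    tr <- simulate_forward(model, sweep, record_migrants = record_migrants,
                           tables = tables)
    sims <- sims + 1L
    if (!is.null(tr)) {
      got <- got + 1L
      pool[[got]] <- tr
    }
  }
  structure(list(trajectories = pool, n_simulated = sims,
                 n_surviving = got,
                 final_freqs = do.call(rbind, lapply(pool, function(tr)
                   tr$final_freqs))),
            class = "sweepsim_trajectory_pool")
}

#' Draw one trajectory from a pool by importance weight
#'
#' Self-normalized importance sampling: trajectories are drawn with
#' probability proportional to their binomial-likelihood weight for the
#' requested sample count.
#'
#' @param pool A `sweepsim_trajectory_pool`.
#' @inheritParams importance_weight
#' @return A `sweepsim_trajectory` with its `weight` field set and attributes
#'   `ess` (importance-sampling effective sample size of the pool) and
#'   `mean_weight`.
#' @export
draw_from_pool <- function(pool, n, x, sample_subpop = NULL) {
  trs <- pool$trajectories
  if (is.null(sample_subpop)) sample_subpop <- trs[[1L]]$origin_subpop
  freqs <- if (!is.null(pool$final_freqs)) pool$final_freqs[, sample_subpop]
           else vapply(trs, function(tr) tr$final_freqs[sample_subpop],
                       numeric(1))
  if (x < 0 || x > n) stop("x must satisfy 0 <= x <= n")
  w <- dbinom(x, n, freqs)
  tot <- sum(w)
  if (tot <= 0)
    stop("all pool importance weights are zero for x = ", x, " of n = ", n,
         " (pool final-frequency range ",
         paste(signif(range(freqs), 3), collapse = " - "), ")")
  i <- sample.int(length(trs), 1L, prob = w)
  tr <- trs[[i]]
  tr$weight <- w[i]
  attr(tr, "ess") <- tot^2 / sum(w^2)
  attr(tr, "mean_weight") <- tot / length(w)
  tr
}

#' Sample a trajectory conditioned on a modern sample count
#'
#' Convenience wrapper: builds a pool with [trajectory_pool()] and draws one
#' trajectory with [draw_from_pool()].  When many conditioned trajectories
#' are needed for the same model, build the pool once and draw repeatedly.
#'
#' @inheritParams trajectory_pool
#' @inheritParams importance_weight
#' @export
sample_trajectory <- function(model, sweep, n, x,
                              sample_subpop = model$sample_subpop,
                              pool_size = 1000L,
                              max_sims = pool_size * 5000L) {
  pool <- trajectory_pool(model, sweep, pool_size, max_sims)
  draw_from_pool(pool, n, x, sample_subpop)
}

# mean survival-conditioned final frequency in the sampled subpopulation
mean_conditional_freq <- function(model, s, t, reps = 200L,
                                  sample_subpop = model$sample_subpop) {
  sw <- sweep_parameters(s = s, origin_gen = t, origin_subpop = sample_subpop)
  tables <- forward_tables(model, t)
  fr <- numeric(0)
  sims <- 0L
  while (length(fr) < reps && sims < reps * 5000L) {
    tr <- simulate_forward(model, sw, record_migrants = FALSE,
                           tables = tables)
    sims <- sims + 1L
    if (!is.null(tr)) fr <- c(fr, tr$final_freqs[sample_subpop])
  }
  if (!length(fr)) stop("no surviving trajectories at t = ", t)
  mean(fr)
}

#' Calibrate the sweep origin generation for a target mean frequency
#'
#' Searches over the origin generation `t` (coarse doubling grid, then
#' bisection on the Monte-Carlo mean survival-conditioned final frequency)
#' until the mean frequency is within `tol` of `target_mean_freq`.
#'
#' @inheritParams trajectory_pool
#' @param s Selection coefficient.
#' @param target_mean_freq Target mean modern frequency, in (0, 1).
#' @param tol Tolerance on the Monte-Carlo mean (default 0.05).
#' @param reps Surviving replicates per evaluation.
#' @param t_max Upper bound on the searched origin generation.
#' @return The calibrated origin generation (integer).
#' @export
tune_origin_generation <- function(model, s, target_mean_freq = 0.5,
                                   tol = 0.05, reps = 200L, t_max = 20000L,
                                   sample_subpop = model$sample_subpop) {
  if (target_mean_freq <= 0 || target_mean_freq >= 1)
    stop("target_mean_freq must be in (0, 1)")
  f_at <- function(t) mean_conditional_freq(model, s, t, reps, sample_subpop)
  lo <- 8L
  f_lo <- f_at(lo)
  if (abs(f_lo - target_mean_freq) <= tol) return(lo)
  if (f_lo > target_mean_freq)
    stop("target frequency unattainable: already exceeded at t = ", lo)
  hi <- lo
  f_hi <- f_lo
  while (f_hi < target_mean_freq) {
    hi <- hi * 2L
    if (hi > t_max)
      stop("target frequency unattainable below t_max = ", t_max)
    f_hi <- f_at(hi)
    if (abs(f_hi - target_mean_freq) <= tol) return(hi)
  }
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    f_mid <- f_at(mid)
    if (abs(f_mid - target_mean_freq) <= tol) return(mid)
    if (f_mid < target_mean_freq) lo <- mid else hi <- mid
  }
  hi
}

# ---------------------------------------------------------------------------
# Columnar TSV serialization (one row per generation x subpopulation)
# ---------------------------------------------------------------------------

#' Write a trajectory to a columnar TSV table
#'
#' One row per generation and subpopulation: favored copy count, total
#' copies, and the realized per-class migrant counts into that
#' subpopulation from every source (columns `mig_fav_from_<i>`,
#' `mig_neut_from_<i>`; NA at the origin generation, which has no forming
#' migration step).
#'
#' @param traj A `sweepsim_trajectory`.
#' @param file Output path.
#' @export
write_trajectory <- function(traj, file) {
  k <- traj$n_subpops
  t_org <- traj$origin_gen
  gens <- rep(0:t_org, each = k)
  sub <- rep(seq_len(k), t_org + 1L)
  df <- data.frame(generation = gens, subpop = sub,
                   fav_count = as.vector(t(traj$counts)),
                   total_copies = as.vector(t(traj$sizes)))
  for (i in seq_len(k)) {
    fav <- rep(NA_real_, length(gens))
    neut <- rep(NA_real_, length(gens))
    if (!is.null(traj$mig_fav)) {
      idx <- gens < t_org
      fav[idx] <- traj$mig_fav[cbind(i, sub[idx], gens[idx] + 1L)]
      neut[idx] <- traj$mig_neut[cbind(i, sub[idx], gens[idx] + 1L)]
    } else if (k == 1L) {
      fav[gens < t_org] <- 0; neut[gens < t_org] <- 0
    }
    df[[paste0("mig_fav_from_", i)]] <- fav
    df[[paste0("mig_neut_from_", i)]] <- neut
  }
  hdr <- sprintf("# sweepsim trajectory: s=%g origin_gen=%d origin_subpop=%d n_subpops=%d",
                 traj$s, t_org, traj$origin_subpop, k)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param file Path to the TSV file.
#' @return A `sweepsim_trajectory`.
#' @export
read_trajectory <- function(file) {
  hdr <- readLines(file, n = 1L)
  meta <- as.list(setNames(
    as.numeric(sub(".*=", "", strsplit(sub("^# sweepsim trajectory: ", "",
                                           hdr), " ")[[1]])),
    sub("=.*", "", strsplit(sub("^# sweepsim trajectory: ", "", hdr),
                            " ")[[1]])))
  df <- read.table(file, header = TRUE, sep = "\t", skip = 1L)
  k <- as.integer(meta$n_subpops)
  t_org <- as.integer(meta$origin_gen)
  counts <- matrix(df$fav_count, t_org + 1L, k, byrow = TRUE)
  sizes <- matrix(df$total_copies, t_org + 1L, k, byrow = TRUE)
  mig_fav <- mig_neut <- NULL
  if (k > 1L) {
    mig_fav <- array(0, c(k, k, t_org))
    mig_neut <- array(0, c(k, k, t_org))
    for (i in seq_len(k)) {
      fav <- matrix(df[[paste0("mig_fav_from_", i)]], t_org + 1L, k,
                    byrow = TRUE)
      neut <- matrix(df[[paste0("mig_neut_from_", i)]], t_org + 1L, k,
                     byrow = TRUE)
      for (j in seq_len(k)) {
        mig_fav[i, j, ] <- fav[seq_len(t_org), j]
        mig_neut[i, j, ] <- neut[seq_len(t_org), j]
      }
    }
  }
  structure(list(
    s = meta$s, origin_gen = t_org,
    origin_subpop = as.integer(meta$origin_subpop), n_subpops = k,
    counts = counts, sizes = sizes, mig_fav = mig_fav, mig_neut = mig_neut,
    final_freqs = counts[1L, ] / sizes[1L, ],
    fixed = all(counts[1L, ] == sizes[1L, ]), weight = NA_real_),
    class = "sweepsim_trajectory")
}
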