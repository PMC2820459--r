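# ---------------------------------------------------------------------------
# Discrete-generation structured coalescent with recombination, conditioned
# on an allele trajectory.  The favored and neutral allelic classes are
# treated as subdivided populations whose per-generation sizes (and realized
# migrant counts) come from the trajectory; beyond the trajectory window the
# process is the ordinary structured coalescent under the demographic model.
# The event engine lives in src/coalescent.cpp.
# ---------------------------------------------------------------------------

# flatten a demographic model for the C++ engine
demography_for_cpp <- function(model) {
  k <- model$n_subpops
  n_ep <- length(model$epochs)
  sizes <- matrix(0, k, n_ep)
  end_sizes <- matrix(NA_real_, k, n_ep)
  mig <- vector("list", n_ep)
  for (e in seq_len(n_ep)) {
    ep <- model$epochs[[e]]
    sizes[, e] <- ep$sizes
    if (!is.null(ep$end_sizes)) end_sizes[, e] <- ep$end_sizes
    mig[[e]] <- ep$migration
  }
  list(start = vapply(model$epochs, function(e) e$start_gen, numeric(1)),
       end = vapply(model$epochs, function(e) e$end_gen, numeric(1)),
       sizes = sizes, end_sizes = end_sizes, migration = mig)
}

trajectory_for_cpp <- function(traj) {
  if (is.null(traj)) return(list())
  k <- traj$n_subpops
  t_org <- traj$origin_gen
  migf <- if (!is.null(traj$mig_fav)) as.numeric(traj$mig_fav)
          else numeric(k * k * t_org)
  mign <- if (!is.null(traj$mig_neut)) as.numeric(traj$mig_neut)
          else numeric(k * k * t_org)
  list(t_org = as.integer(t_org), fav = traj$counts * 1.0,
       tot = traj$sizes * 1.0, migf = migf, mign = mign)
}

#' Draw a locus recombination rate
#'
#' With `variable = FALSE` returns `mean_rate` unchanged; with
#' `variable = TRUE` returns an exponential random variate with that mean
#' (the variable-recombination regime: one rate per simulated locus).
#'
#' @param mean_rate Mean recombination rate per bp per generation
#'   (1 cM/Mb = 1e-8).
#' @param variable Draw an exponential variate instead of the constant rate.
#' @return A single rate (per bp per generation).
#' @export
draw_recomb_rate <- function(mean_rate = 1e-8, variable = FALSE) {
  if (mean_rate <= 0) stop("mean_rate must be > 0")
  if (!variable) return(mean_rate)
  rexp(1L, rate = 1 / mean_rate)
}

#' Simulate a genealogy conditioned on an allele trajectory
#'
#' Runs the backward-in-time structured coalescent with recombination for a
#' sample of `n` chromosomes from one subpopulation, `x` of which carry the
#' favored allele at the selected site.  Event waiting times per
#' (subpopulation, allelic class) are generated by inverting per-generation
#' cumulative hazards with standard-exponential variates; recombination
#' waiting times are continuous exponentials with rate `recomb_rate` times
#' the total ancestral-material span, rounded to generation steps; the next
#' event is the one with the shortest wait.  Crossover products that do not
#' inherit the selected site are assigned the favored class with probability
#' equal to the favored-allele frequency in their subpopulation at that
#' generation.  At the trajectory's origin generation the last favored
#' lineage mutates into the neutral class.
#'
#' @param model A [demographic_model()].
#' @param traj A `sweepsim_trajectory`, or `NULL` for a neutral simulation.
#' @param n Sample size in chromosomes.
#' @param x Number of sampled chromosomes carrying the favored allele
#'   (0 for neutral simulations).
#' @param region_length Region length in bp.
#' @param recomb_rate Recombination rate per bp per generation.
#' @param sample_subpop Sampled subpopulation index.
#' @param selected_pos Position of the selected site (default: region
#'   midpoint).
#' @param max_events Budget on executed events (guards against runaway
#'   recombination).
#' @return Object of class `sweepsim_genealogy`: `nodes` (data frame with
#'   0-based `id`, `time` in generations, `subpop`), `edges` (data frame
#'   `parent`, `child`, `left`, `right`; 0-based ids, half-open bp
#'   intervals), `n_samples`, `sample_class`, `sample_subpop`,
#'   `selected_pos`, `region_length`, `n_class_switch`, `switch_gen`.
#' @export
simulate_genealogy <- function(model, traj = NULL, n, x = 0L,
                               region_length, recomb_rate = 1e-8,
                               sample_subpop = model$sample_subpop,
                               selected_pos = region_length / 2,
                               max_events = 2e7) {
  n <- as.integer(n); x <- as.integer(x)
  if (n < 2L) stop("need at least 2 sampled chromosomes")
  if (x < 0L || x > n) stop("x must satisfy 0 <= x <= n")
  if (x > 0L && is.null(traj))
    stop("favored samples require an allele trajectory")
  if (!is.null(traj)) {
    if (traj$n_subpops != model$n_subpops)
      stop("trajectory and model subpopulation counts differ")
    fav0 <- traj$counts[1L, sample_subpop]
    tot0 <- traj$sizes[1L, sample_subpop]
    if (x > fav0)
      stop("sample_config inconsistent with trajectory: x = ", x,
           " favored sampled but only ", fav0, " favored copies exist")
    if (n - x > tot0 - fav0)
      stop("sample_config inconsistent with trajectory: too few neutral copies")
  }
  samp_subpop <- rep(as.integer(sample_subpop) - 1L, n)
  samp_class <- c(rep(1L, x), rep(0L, n - x))
  res <- .sim_genealogy_cpp(region_length, selected_pos, recomb_rate,
                            samp_subpop, samp_class,
                            demography_for_cpp(model),
                            trajectory_for_cpp(traj), max_events)
  structure(list(
    nodes = data.frame(id = seq_along(res$node_time) - 1L,
                       time = res$node_time,
                       subpop = res$node_subpop + 1L),
    edges = data.frame(parent = res$edge_parent, child = res$edge_child,
                       left = res$edge_left, right = res$edge_right),
    n_samples = n, sample_class = samp_class,
    sample_subpop = as.integer(sample_subpop),
    selected_pos = selected_pos, region_length = region_length,
    recomb_rate = recomb_rate,
    n_class_switch = res$n_class_switch, switch_gen = res$switch_gen,
    n_events = res$n_events), class = "sweepsim_genealogy")
}

#' @export
print.sweepsim_genealogy <- function(x, ...) {
  cat("sweepsim genealogy: ", x$n_samples, " samples (",
      sum(x$sample_class), " favored), ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges, region ", x$region_length, " bp\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Hazard tables (inspectable form of the lookup tables that drive the
# backward simulation)
# ---------------------------------------------------------------------------

#' Build cumulative hazard lookup tables from a trajectory
#'
#' For each (subpopulation, allelic class): the cumulative pairwise
#' coalescent hazard over backward generations, with per-generation increment
#' `1 / (class size in copies)` (`Inf` once the class size reaches 1, which
#' forces any remaining lineages of the class to coalesce); the cumulative
#' migration-out hazard with increment `(realized migrants into the
#' subpopulation, backward out of it) / class size`; and the per-generation
#' conditional destination distribution given that a migration occurred.
#'
#' @param traj A `sweepsim_trajectory`.
#' @param model The [demographic_model()] the trajectory was simulated under.
#' @return List with arrays `coal_cum` (gen x subpop x class),
#'   `mig_cum` (gen x subpop x class) and `mig_dest`
#'   (gen x origin x destination x class); generation `g` is row `g + 1`,
#'   class 1 = neutral, class 2 = favored.
#' @export
build_hazard_tables <- function(traj, model) {
  k <- traj$n_subpops
  t_org <- traj$origin_gen
  if (!is.null(model) && model$n_subpops != k)
    stop("trajectory and model subpopulation counts differ")
  fav <- traj$counts
  neut <- traj$sizes - traj$counts
  size <- array(c(neut, fav), c(t_org + 1L, k, 2L))
  inc <- ifelse(size >= 2, 1 / size, ifelse(size == 1, Inf, 0))
  coal_cum <- apply(inc, c(2, 3), cumsum)
  mig_inc <- array(0, c(t_org + 1L, k, 2L))
  mig_dest <- array(0, c(t_org + 1L, k, k, 2L))
  if (k > 1L && !is.null(traj$mig_fav)) {
    for (g in 0:(t_org - 1L)) {
      for (d in seq_len(k)) {
        for (cls in 1:2) {
          m <- if (cls == 2L) traj$mig_fav[, d, g + 1L]
               else traj$mig_neut[, d, g + 1L]
          m[d] <- 0
          tot_in <- sum(m)
          sz <- size[g + 1L, d, cls]
          if (sz > 0 && tot_in > 0) {
            mig_inc[g + 1L, d, cls] <- tot_in / sz
            mig_dest[g + 1L, d, , cls] <- m / tot_in
          }
        }
      }
    }
  }
  mig_cum <- apply(mig_inc, c(2, 3), cumsum)
  dimnames(coal_cum) <- dimnames(mig_cum) <-
    list(NULL, NULL, c("neutral", "favored"))
  list(coal_cum = coal_cum, mig_cum = mig_cum, mig_dest = mig_dest)
}

# ---------------------------------------------------------------------------
# Genealogy utilities
# ---------------------------------------------------------------------------

#' Parent map of the marginal tree at a position
#'
#' @param gen A `sweepsim_genealogy`.
#' @param pos Position in bp.
#' @return Integer vector over node ids (1-based indexing into nodes): entry
#'   `i` is the 0-based parent id of node `i - 1` at `pos`, or `NA` if the
#'   node has no parent there.
#' @export
marginal_parents <- function(gen, pos) {
  e <- gen$edges
  sel <- e$left <= pos & pos < e$right
  par <- rep(NA_integer_, nrow(gen$nodes))
  par[e$child[sel] + 1L] <- e$parent[sel]
  par
}

# root id and time of the marginal tree over the samples at pos
marginal_root <- function(gen, pos) {
  par <- marginal_parents(gen, pos)
  climb <- function(v) {
    while (!is.na(par[v + 1L])) v <- par[v + 1L]
    v
  }
  roots <- unique(vapply(0:(gen$n_samples - 1L), climb, integer(1)))
  list(roots = roots, times = gen$nodes$time[roots + 1L])
}

#' Time to the most recent common ancestor at a position
#'
#' @inheritParams marginal_parents
#' @return TMRCA in generations (errors if the position has multiple roots).
#' @export
tmrca <- function(gen, pos = gen$selected_pos) {
  r <- marginal_root(gen, pos)
  if (length(r$roots) != 1L)
    stop("position ", pos, " has ", length(r$roots), " roots")
  r$times
}

#' Validate structural invariants of a genealogy
#'
#' Checks, on a grid of positions, that the marginal tree has a single root
#' over the samples, that child times are strictly below parent times, and
#' that every sample's ancestry is covered.
#'
#' @inheritParams marginal_parents
#' @param n_positions Grid size.
#' @return `TRUE` invisibly; errors describe any violation.
#' @export
check_genealogy <- function(gen, n_positions = 20L) {
  e <- gen$edges
  tt <- gen$nodes$time
  if (any(tt[e$child + 1L] >= tt[e$parent + 1L]))
    stop("child time >= parent time")
  grid <- seq(0, gen$region_length * (1 - 1e-9),
              length.out = n_positions)
  for (pos in grid) {
    r <- marginal_root(gen, pos)
    if (length(r$roots) != 1L)
      stop("multiple roots at position ", pos)
  }
  invisible(TRUE)
}

#' Export a genealogy's node and edge tables to TSV
#'
#' @inheritParams marginal_parents
#' @param prefix Output path prefix; writes `<prefix>_nodes.tsv` and
#'   `<prefix>_edges.tsv`.
#' @export
write_genealogy <- function(gen, prefix) {
  write.table(gen$nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(gen$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Marginal tree at a position as an `ape` phylo object
#'
#' Debug-scale export; unary nodes introduced by recombination are collapsed.
#'
#' @inheritParams marginal_parents
#' @return An `ape::phylo`.
#' @export
marginal_tree_phylo <- function(gen, pos) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("package 'ape' is required for newick export")
  par <- marginal_parents(gen, pos)
  n <- gen$n_samples
  children <- split(which(!is.na(par)) - 1L, par[!is.na(par)])
  root <- marginal_root(gen, pos)
  if (length(root$roots) != 1L) stop("position has multiple roots")
  times <- gen$nodes$time
  emit <- function(v) {
    kids <- children[[as.character(v)]]
    if (is.null(kids)) return(paste0("s", v + 1L))
    subs <- vapply(kids, function(k)
      paste0(emit(k), ":", format(times[v + 1L] - times[k + 1L],
                                  digits = 12)), character(1))
    paste0("(", paste(subs, collapse = ","), ")")
  }
  txt <- paste0(emit(root$roots), ";")
  ape::collapse.singles(ape::read.tree(text = txt))
}
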