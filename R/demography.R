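#' @useDynLib sweepsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rmultinom rexp rpois runif quantile sd var
#'   dbinom nls coef setNames
#' @importFrom utils head tail write.table read.table modifyList
NULL

# ---------------------------------------------------------------------------
# Multi-population, multi-epoch demographic histories.
#
# Time is measured in discrete generations before present (present = 0).
# Epochs are half-open integer intervals [start_gen, end_gen), youngest first;
# the oldest epoch is open-ended (end_gen = Inf).  Diploid sizes N_d are per
# subpopulation.  The migration matrix uses the forward-time convention fixed
# for the whole package:
#
#   m[i, j] = fraction of subpopulation j's offspring drawn from
#             subpopulation i in one forward generation.
#
# Backward-time lineage movement is derived from this convention.
# ---------------------------------------------------------------------------

#' Construct one demographic epoch
#'
#' @param start_gen Integer generations before present (inclusive).
#' @param end_gen Integer generations before present (exclusive); `Inf` for
#'   the oldest epoch.
#' @param sizes Numeric vector of per-subpopulation diploid sizes.
#' @param migration Square matrix; `migration[i, j]` is the forward-time
#'   per-generation fraction of subpopulation j's offspring drawn from
#'   subpopulation i.  Defaults to no migration.
#' @param end_sizes Optional per-subpopulation diploid sizes at `end_gen`;
#'   when supplied, sizes are interpolated exponentially (log-linearly)
#'   per generation across the epoch.  Only allowed for finite epochs.
#' @return A list of class `sweepsim_epoch`.
#' @export
epoch <- function(start_gen, end_gen, sizes, migration = NULL,
                  end_sizes = NULL) {
  k <- length(sizes)
  if (is.null(migration)) migration <- matrix(0, k, k)
  migration <- as.matrix(migration)
  e <- structure(
    list(start_gen = as.numeric(start_gen), end_gen = as.numeric(end_gen),
         sizes = as.numeric(sizes), migration = migration,
         end_sizes = if (!is.null(end_sizes)) as.numeric(end_sizes)),
    class = "sweepsim_epoch")
  validate_epoch(e)
  e
}

validate_epoch <- function(e) {
  k <- length(e$sizes)
  if (k < 1L) stop("epoch needs at least one subpopulation")
  if (any(e$sizes < 1)) stop("all diploid sizes must be >= 1")
  if (e$start_gen < 0) stop("start_gen must be >= 0")
  if (!(e$end_gen > e$start_gen)) stop("end_gen must exceed start_gen")
  m <- e$migration
  if (!is.matrix(m) || nrow(m) != k || ncol(m) != k)
    stop("migration must be a ", k, "x", k, " matrix")
  if (any(m < 0)) stop("migration rates must be non-negative")
  if (any(diag(m) != 0)) stop("migration diagonal entries must be 0")
  if (any(rowSums(m) >= 1) || any(colSums(m) >= 1))
    stop("migration fractions per subpopulation must sum to < 1")
  if (!is.null(e$end_sizes)) {
    if (!is.finite(e$end_gen))
      stop("exponential growth requires a finite epoch")
    if (length(e$end_sizes) != k || any(e$end_sizes < 1))
      stop("end_sizes must match subpopulation count and be >= 1")
  }
  invisible(e)
}

#' Construct a demographic model
#'
#' @param epochs List of [epoch()] objects, youngest first, tiling
#'   `[0, Inf)` with no gaps or overlaps.
#' @param labels Character vector of subpopulation names.
#' @param sample_subpop Index of the subpopulation samples are drawn from
#'   (used by downstream simulation defaults).
#' @param name Optional model name.
#' @return A list of class `sweepsim_demography`.
#' @export
demographic_model <- function(epochs, labels = NULL, sample_subpop = 1L,
                              name = "custom") {
  if (!length(epochs)) stop("at least one epoch required")
  k <- length(epochs[[1]]$sizes)
  if (is.null(labels)) labels <- paste0("pop", seq_len(k))
  m <- structure(
    list(n_subpops = k, epochs = epochs, labels = as.character(labels),
         sample_subpop = as.integer(sample_subpop), name = name),
    class = "sweepsim_demography")
  validate_demography(m)
  m
}

validate_demography <- function(model) {
  k <- model$n_subpops
  if (length(model$labels) != k) stop("labels must match n_subpops")
  if (model$sample_subpop < 1L || model$sample_subpop > k)
    stop("sample_subpop out of range")
  cur <- 0
  n_ep <- length(model$epochs)
  for (i in seq_len(n_ep)) {
    e <- model$epochs[[i]]
    validate_epoch(e)
    if (length(e$sizes) != k)
      stop("all epochs must have ", k, " subpopulations")
    if (e$start_gen != cur)
      stop("epochs must tile [0, Inf): epoch ", i, " starts at ",
           e$start_gen, ", expected ", cur)
    cur <- e$end_gen
  }
  if (is.finite(cur))
    stop("oldest epoch must be open-ended (end_gen = Inf)")
  invisible(model)
}

#' @export
print.sweepsim_demography <- function(x, ...) {
  cat("Demographic model '", x$name, "': ", x$n_subpops, " subpopulation(s) [",
      paste(x$labels, collapse = ", "), "], ", length(x$epochs),
      " epoch(s)\n", sep = "")
  for (e in x$epochs)
    cat(sprintf("  [%g, %g): N = %s%s\n", e$start_gen, e$end_gen,
                paste(round(e$sizes), collapse = "/"),
                if (any(e$migration > 0)) "  (migration)" else ""))
  invisible(x)
}

epoch_index_at <- function(model, gen) {
  for (i in seq_along(model$epochs)) {
    e <- model$epochs[[i]]
    if (gen >= e$start_gen && gen < e$end_gen) return(i)
  }
  stop("generation ", gen, " not covered by any epoch")  # unreachable
}

#' Diploid size of a subpopulation at a generation
#'
#' @param model A [demographic_model()].
#' @param subpop Subpopulation index (1-based).
#' @param gen Integer generations before present (>= 0).
#' @return Diploid size (individuals), rounded to an integer.
#' @export
size_at <- function(model, subpop, gen) {
  if (any(gen < 0)) stop("gen must be >= 0")
  if (subpop < 1L || subpop > model$n_subpops) stop("subpop out of range")
  vapply(gen, function(g) {
    e <- model$epochs[[epoch_index_at(model, g)]]
    if (is.null(e$end_sizes)) return(e$sizes[subpop])
    # exponential interpolation: size = start at start_gen, end at end_gen
    frac <- (g - e$start_gen) / (e$end_gen - e$start_gen)
    round(exp((1 - frac) * log(e$sizes[subpop]) +
              frac * log(e$end_sizes[subpop])))
  }, numeric(1))
}

#' Forward migration matrix at a generation
#'
#' `migration_at(model, gen)[i, j]` is the fraction of subpopulation j's
#' offspring drawn from subpopulation i at generation `gen`.
#'
#' @inheritParams size_at
#' @return Square numeric matrix.
#' @export
migration_at <- function(model, gen) {
  if (gen < 0) stop("gen must be >= 0")
  model$epochs[[epoch_index_at(model, gen)]]$migration
}

# per-subpop diploid sizes at one generation (vector)
sizes_at <- function(model, gen) {
  vapply(seq_len(model$n_subpops), function(d) size_at(model, d, gen),
         numeric(1))
}

# ---------------------------------------------------------------------------
# Config (YAML) serialization
# ---------------------------------------------------------------------------

#' Read a demographic model from a YAML config
#'
#' The schema mirrors [demographic_model()]: top-level fields `labels`,
#' `sample_subpop` (label or index), `name`, and `epochs`, each epoch with
#' `start_gen`, `end_gen` (`.inf` for the oldest), `sizes`, optional
#' `end_sizes` (exponential growth within the epoch) and `migration`
#' (row-major list of rows, forward-time convention).
#'
#' @param x Path to a YAML file, or an already-parsed list.
#' @return A [demographic_model()].
#' @export
demography_from_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  labels <- as.character(cfg$labels)
  k <- length(labels)
  eps <- lapply(cfg$epochs, function(e) {
    mig <- if (is.null(e$migration)) matrix(0, k, k)
           else matrix(unlist(e$migration), nrow = k, byrow = TRUE)
    end_gen <- e$end_gen
    if (is.character(end_gen) || is.null(end_gen)) end_gen <- Inf
    epoch(e$start_gen, end_gen, unlist(e$sizes), mig,
          end_sizes = if (!is.null(e$end_sizes)) unlist(e$end_sizes))
  })
  samp <- cfg$sample_subpop
  if (is.null(samp)) samp <- 1L
  if (is.character(samp)) samp <- match(samp, labels)
  demographic_model(eps, labels, sample_subpop = samp,
                    name = if (is.null(cfg$name)) "config" else cfg$name)
}

#' Serialize a demographic model to a config list (YAML-compatible)
#'
#' @param model A [demographic_model()].
#' @param file Optional path; when given the YAML is written there.
#' @return The config list, invisibly when written to a file.
#' @export
demography_to_config <- function(model, file = NULL) {
  cfg <- list(
    name = model$name,
    labels = as.list(model$labels),
    sample_subpop = model$labels[model$sample_subpop],
    epochs = lapply(model$epochs, function(e) {
      out <- list(start_gen = e$start_gen,
                  end_gen = if (is.finite(e$end_gen)) e$end_gen else Inf,
                  sizes = as.list(e$sizes))
      if (!is.null(e$end_sizes)) out$end_sizes <- as.list(e$end_sizes)
      if (any(e$migration > 0))
        out$migration <- lapply(seq_len(nrow(e$migration)),
                                function(i) as.list(e$migration[i, ]))
      out
    }))
  if (!is.null(file)) {
    yaml::write_yaml(cfg, file)
    return(invisible(cfg))
  }
  cfg
}

# ---------------------------------------------------------------------------
# Presets
# ---------------------------------------------------------------------------

preset_config_path <- function() {
  system.file("extdata", "demographies.yaml", package = "sweepsim",
              mustWork = TRUE)
}

#' Build one of the packaged demographic presets
#'
#' Four presets are shipped: `constant` (one panmictic population),
#' `expansion` (an African-role population that grew), `expansion_migration`
#' (three populations, African-role expansion, low symmetric migration) and
#' `bottleneck_migration` (three populations, European-role bottleneck, low
#' symmetric migration).  Parameter values are editable configuration
#' defaults (see `inst/extdata/demographies.yaml`), documented approximations
#' of published multi-population calibrations of human history; they are not
#' estimates in their own right.
#'
#' @param name One of `"constant"`, `"expansion"`, `"expansion_migration"`,
#'   `"bottleneck_migration"`.
#' @param overrides Optional named list merged over the preset config before
#'   validation (advanced use).
#' @param config_path Optional alternative YAML file with the same schema.
#' @return A [demographic_model()] with attribute `"sweep_defaults"` holding
#'   the preset's default selection parameters (`s`, `origin_gen`).
#' @export
build_preset <- function(name, overrides = NULL,
                         config_path = preset_config_path()) {
  all_cfg <- yaml::read_yaml(config_path)
  if (!name %in% names(all_cfg))
    stop("unknown preset '", name, "'; available: ",
         paste(names(all_cfg), collapse = ", "))
  cfg <- all_cfg[[name]]
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  model <- demography_from_config(cfg)
  model$name <- name
  attr(model, "sweep_defaults") <- cfg$sweep_defaults
  model
}
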