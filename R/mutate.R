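# ---------------------------------------------------------------------------
# Infinite-sites mutations, discovery-panel ascertainment, diploid pairing,
# and haplotype-sample I/O (ms-style blocks, minimal phased VCF).
# ---------------------------------------------------------------------------

#' Construct a haplotype sample
#'
#' @param alleles 0/1 integer matrix, chromosomes x sites (0 = ancestral).
#' @param positions Strictly increasing bp positions (0-based, may be
#'   fractional internally).
#' @param region_length Region length in bp.
#' @param selected_site Column index of the selected site, or `NA`.
#' @param favored_allele Allele coding the favored class at that column.
#' @param diploid_pairs Two-column matrix of chromosome indices, or `NULL`.
#' @return Object of class `sweepsim_haplotypes`.
#' @export
haplotype_sample <- function(alleles, positions, region_length,
                             selected_site = NA_integer_, favored_allele = 1L,
                             diploid_pairs = NULL) {
  alleles <- as.matrix(alleles)
  if (length(positions) != ncol(alleles))
    stop("positions must match the number of columns")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  structure(list(alleles = alleles, positions = as.numeric(positions),
                 region_length = region_length,
                 selected_site = selected_site,
                 favored_allele = favored_allele,
                 diploid_pairs = diploid_pairs),
            class = "sweepsim_haplotypes")
}

#' @export
print.sweepsim_haplotypes <- function(x, ...) {
  cat("sweepsim haplotypes: ", nrow(x$alleles), " chromosomes x ",
      ncol(x$alleles), " sites over ", x$region_length, " bp",
      if (!is.na(x$selected_site)) paste0("; selected site at column ",
                                          x$selected_site), "\n", sep = "")
  invisible(x)
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Each edge receives a Poisson number of mutations with mean
#' `mu x interval length x edge duration`; each mutation gets a unique
#' uniform position within the edge's interval and its carriers are the
#' samples below the edge at that position.  The selected site itself is
#' emitted as an extra column whose derived allele marks the favored class
#' (only when it is polymorphic in the sample).
#'
#' @param gen A `sweepsim_genealogy`.
#' @param mu Mutation rate per bp per generation (default 2.2e-8).
#' @return A [haplotype_sample()]; every column is polymorphic in the sample.
#' @export
drop_mutations <- function(gen, mu = 2.2e-8) {
  n <- gen$n_samples
  res <- .drop_mutations_cpp(n, gen$nodes$time, gen$edges$parent,
                             gen$edges$child, gen$edges$left,
                             gen$edges$right, mu)
  pos <- res$positions
  S <- length(pos)
  X <- matrix(0L, n, S)
  for (j in seq_len(S)) X[res$carriers[[j]] + 1L, j] <- 1L
  sel_col <- NA_integer_
  x_fav <- sum(gen$sample_class)
  if (x_fav > 0L && x_fav < n) {
    pos <- c(pos, gen$selected_pos)
    X <- cbind(X, as.integer(gen$sample_class))
    S <- S + 1L
  }
  o <- order(pos)
  pos <- pos[o]
  X <- X[, o, drop = FALSE]
  # infinite sites: continuous positions are a.s. unique, but guard anyway
  dup <- which(duplicated(pos))
  if (length(dup)) {
    keep <- setdiff(seq_len(S), dup)
    pos <- pos[keep]; X <- X[, keep, drop = FALSE]
  }
  sel_col <- if (x_fav > 0L && x_fav < n) which(pos == gen$selected_pos)[1]
             else NA_integer_
  haplotype_sample(X, pos, gen$region_length, selected_site = sel_col)
}

#' Apply discovery-panel ascertainment bias
#'
#' Emulates a two-stage SNP discovery design: a uniformly chosen subsample
#' of `round(frac * n)` chromosomes is designated the discovery panel and
#' only sites polymorphic within the panel are retained (genotypes of the
#' full panel are unchanged at retained sites).  The selected site is
#' subject to the same filter unless `force_retain_selected` is set.
#'
#' @param sample A `sweepsim_haplotypes`.
#' @param frac Fraction of chromosomes in the discovery panel.  The default
#'   draws a fresh uniform fraction on \[0.13, 0.33\] per call, mirroring a
#'   13-33% discovery subsample.
#' @param force_retain_selected Keep the selected-site column regardless of
#'   the panel filter (default `FALSE`).
#' @return A `sweepsim_haplotypes` with the filtered site set; attribute
#'   `"ascertainment_frac"` records the fraction used.
#' @export
apply_ascertainment <- function(sample, frac = runif(1, 0.13, 0.33),
                                force_retain_selected = FALSE) {
  n <- nrow(sample$alleles)
  m <- round(frac * n)
  if (m < 2L) stop("discovery subsample must contain at least 2 chromosomes")
  panel <- sample.int(n, m)
  cs <- colSums(sample$alleles[panel, , drop = FALSE])
  keep <- cs > 0L & cs < m
  if (force_retain_selected && !is.na(sample$selected_site))
    keep[sample$selected_site] <- TRUE
  new_sel <- NA_integer_
  if (!is.na(sample$selected_site) && keep[sample$selected_site])
    new_sel <- sum(keep[seq_len(sample$selected_site)])
  out <- haplotype_sample(sample$alleles[, keep, drop = FALSE],
                          sample$positions[keep], sample$region_length,
                          selected_site = new_sel,
                          favored_allele = sample$favored_allele,
                          diploid_pairs = sample$diploid_pairs)
  attr(out, "ascertainment_frac") <- frac
  out
}

#' Group chromosomes into random diploid pairs
#'
#' @param sample A `sweepsim_haplotypes` with an even number of chromosomes.
#' @return The sample with `diploid_pairs` set to a uniform random perfect
#'   matching.
#' @export
pair_diploids <- function(sample) {
  n <- nrow(sample$alleles)
  if (n %% 2L != 0L) stop("diploid pairing requires an even chromosome count")
  perm <- sample.int(n)
  sample$diploid_pairs <- matrix(perm, ncol = 2L, byrow = TRUE)
  sample
}

# ---------------------------------------------------------------------------
# ms-style writer/reader (segsites/positions blocks, positions in [0,1))
# ---------------------------------------------------------------------------

#' Write haplotype samples as ms-style output
#'
#' @param samples A `sweepsim_haplotypes` or list of them (replicates).
#' @param file Output path.
#' @param cmd Command line recorded on the header line.
#' @export
write_ms <- function(samples, file, cmd = "sweepsim") {
  if (inherits(samples, "sweepsim_haplotypes")) samples <- list(samples)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(cmd, ""), con)
  for (s in samples) {
    writeLines("//", con)
    writeLines(paste("segsites:", ncol(s$alleles)), con)
    writeLines(paste("positions:",
                     paste(sprintf("%.8f", s$positions / s$region_length),
                           collapse = " ")), con)
    writeLines(apply(s$alleles, 1L, paste, collapse = ""), con)
    writeLines("", con)
  }
  invisible(file)
}

#' Read ms-style output
#'
#' @param file Path to an ms-style file.
#' @param region_length Region length used to rescale unit positions to bp.
#' @return List of `sweepsim_haplotypes` replicates.
#' @export
read_ms <- function(file, region_length = 1) {
  lines <- readLines(file)
  starts <- grep("^//", lines)
  lapply(starts, function(i) {
    seg <- as.integer(sub("segsites:\\s*", "", lines[i + 1L]))
    pos <- as.numeric(strsplit(sub("positions:\\s*", "", lines[i + 2L]),
                               "\\s+")[[1]]) * region_length
    j <- i + 3L
    hap <- character(0)
    while (j <= length(lines) && grepl("^[01]+$", lines[j])) {
      hap <- c(hap, lines[j]); j <- j + 1L
    }
    X <- do.call(rbind, lapply(strsplit(hap, ""), as.integer))
    if (seg == 0L) X <- matrix(0L, length(hap), 0L)
    haplotype_sample(X, pos, region_length)
  })
}

# ---------------------------------------------------------------------------
# Minimal phased VCF (v4.2) writer and reader
# ---------------------------------------------------------------------------

#' Write a haplotype sample as a minimal phased VCF
#'
#' VCFv4.2, phased GT with `|`, 1-based integer positions (internal 0-based
#' fractional positions are floored and bumped to stay unique), ancestral
#' allele recorded in the INFO `AA` field (always the REF allele here).
#'
#' @param sample A `sweepsim_haplotypes`; chromosomes are paired into
#'   diploid genotype columns (using `diploid_pairs` when present,
#'   consecutive pairing otherwise).
#' @param file Output path.
#' @param chrom Chromosome name.
#' @export
write_vcf <- function(sample, file, chrom = "1") {
  X <- sample$alleles
  n <- nrow(X); S <- ncol(X)
  pairs <- sample$diploid_pairs
  if (is.null(pairs)) {
    if (n %% 2L != 0L) stop("VCF output requires an even chromosome count")
    pairs <- matrix(seq_len(n), ncol = 2L, byrow = TRUE)
  }
  pos1 <- floor(sample$positions) + 1L
  while (any(dup <- duplicated(pos1))) pos1[dup] <- pos1[dup] + 1L
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", chrom, ",length=",
                  ceiling(sample$region_length) + S, ">"),
           '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT",
                   paste0("ind", seq_len(nrow(pairs)))), collapse = "\t"))
  gt <- matrix("", S, nrow(pairs))
  for (d in seq_len(nrow(pairs)))
    gt[, d] <- paste0(X[pairs[d, 1L], ], "|", X[pairs[d, 2L], ])
  body <- vapply(seq_len(S), function(j) {
    paste(c(chrom, pos1[j], ".", "A", "G", ".", "PASS", "AA=A", "GT",
            gt[j, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Read phased haplotypes from a VCF
#'
#' Requires phased GT fields and an ancestral-allele `AA` INFO tag to
#' polarize alleles (0 = ancestral).  Unphased genotypes are an error naming
#' the first offending record.
#'
#' @param file Path to a VCF.
#' @param region_length Region length in bp (default: max position + 1).
#' @return A `sweepsim_haplotypes` with `diploid_pairs` set to the VCF
#'   sample columns.
#' @export
read_vcf_haplotypes <- function(file, region_length = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package 'vcfR' is required to read VCF input")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info <- fix[, "INFO"]
  aa <- sub(".*AA=([^;]+).*", "\\1", info)
  if (any(!grepl("AA=", info)))
    stop("ancestral-allele polarity requires an AA INFO tag; first site ",
         "without one at position ", fix[which(!grepl("AA=", info))[1], "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  unph <- matrix(grepl("/", gt, fixed = TRUE), nrow(gt))
  if (any(unph)) {
    w <- which(unph, arr.ind = TRUE)[1, ]
    stop("unphased genotype at record ", rownames(gt)[w[1]],
         " sample ", colnames(gt)[w[2]])
  }
  split_gt <- function(row) {
    m <- do.call(rbind, strsplit(gt[row, ], "|", fixed = TRUE))
    as.integer(t(m))   # chrom-major: ind1_hapA, ind1_hapB, ind2_hapA, ...
  }
  S <- nrow(gt)
  mat <- vapply(seq_len(S), split_gt, integer(2L * ncol(gt)))
  # polarize: allele index 0 is REF; if AA == ALT flip
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  flip <- aa == alt
  if (any(flip)) mat[, flip] <- 1L - mat[, flip]
  if (any(aa != ref & aa != alt))
    stop("AA allele matches neither REF nor ALT at position ",
         fix[which(aa != ref & aa != alt)[1], "POS"])
  pos <- as.numeric(fix[, "POS"]) - 1
  if (is.null(region_length)) region_length <- max(pos) + 1
  n <- nrow(mat)
  haplotype_sample(mat, pos, region_length,
                   diploid_pairs = matrix(seq_len(n), ncol = 2L,
                                          byrow = TRUE))
}
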