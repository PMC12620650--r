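#' Multidimensional joint site frequency spectra
#'
#' A joint SFS over k populations is a k-dimensional array of site counts
#' indexed by the derived-allele count in each population (axis p has length
#' haploid size of p, plus one).  The all-ancestral corner cell is held
#' outside the array in `monomorphic` so both fixed corners stay
#' addressable.  `kind` distinguishes observed integer counts from expected
#' per-site probabilities produced by [expected_sfs()].
#'
#' @param panel population panel: tibble with columns `pop` and `haploids`
#'   (see [population_panel()]).
#' @param counts k-dimensional array (counts or probabilities).
#' @param monomorphic number (or probability) of sites ancestral in every
#'   population.
#' @param mask optional logical array marking entries excluded from
#'   estimation.
#' @param kind `"observed"` or `"expected"`.
#' @return an object of class `joint_sfs`.
#' @export
joint_sfs <- function(panel, counts, monomorphic = 0, mask = NULL,
                      kind = "observed") {
  dims <- panel$haploids + 1L
  counts <- array(counts, dim = dims)
  structure(list(panel = panel, counts = counts, monomorphic = monomorphic,
                 mask = mask, kind = kind),
            class = "joint_sfs")
}

#' Define a population panel
#'
#' Fixes the population order (and thereby the axis order of every joint
#' SFS built from it) together with per-population haploid sample sizes.
#'
#' @param pops character vector of population names (unique).
#' @param haploids integer vector of haploid sample sizes (2 x diploids).
#' @return tibble with columns `pop`, `haploids`.
#' @export
population_panel <- function(pops, haploids) {
  if (anyDuplicated(pops)) abort("population names must be unique")
  if (any(haploids < 1)) abort("haploid sizes must be >= 1")
  tibble(pop = pops, haploids = as.integer(haploids))
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat("<joint_sfs> [", x$kind, "] ", nrow(x$panel), " populations: ",
      paste0(x$panel$pop, "(", x$panel$haploids, ")", collapse = ", "), "\n",
      sep = "")
  cat("  polymorphic total: ", sum(x$counts), "; monomorphic: ",
      x$monomorphic, if (!is.null(x$mask))
        paste0("; masked cells: ", sum(x$mask)), "\n", sep = "")
  invisible(x)
}

#' Tidy a joint SFS into a long tibble
#'
#' @param x a `joint_sfs`.
#' @param drop_zero drop empty cells (default TRUE).
#' @param ... unused.
#' @return tibble with one derived-count column per population plus `count`
#'   and (when masked) `masked`.
#' @export
tidy.joint_sfs <- function(x, drop_zero = TRUE, ...) {
  dims <- dim(x$counts)
  idx <- which(x$counts != 0 | !drop_zero)
  co <- arrayInd(idx, dims) - 1L
  colnames(co) <- x$panel$pop
  out <- bind_cols(as_tibble(co), tibble(count = x$counts[idx]))
  if (!is.null(x$mask)) out$masked <- x$mask[idx]
  out
}

# linear 1-based index of a matrix of per-pop derived counts (rows = sites)
sfs_linear_index <- function(derived, dims) {
  stride <- cumprod(c(1L, head(dims, -1L)))
  as.integer(derived %*% stride) + 1L
}

#' Build a joint SFS from a genotype matrix
#'
#' Tallies, for every site, the derived-allele count in each panel
#' population into the unfolded multidimensional SFS.  All calls must be
#' non-missing and every site must have a known ancestral state (guaranteed
#' after [apply_sfs_filters()]).
#'
#' @param g a `geno_matrix`.
#' @param panel a [population_panel()]; haploid sizes must equal 2 x the
#'   number of panel diploids present in `g`.
#' @param genome_length optional total number of usable sites (bp) the
#'   variants were called from; the excess over `n_sites(g)` is added to the
#'   monomorphic cell.  Defaults to the `genome_length` attribute of `g` if
#'   present.
#' @return a `joint_sfs` of kind `"observed"`.
#' @export
build_joint_sfs <- function(g, panel, genome_length = NULL) {
  if (anyNA(g$calls)) abort("genotype calls contain missing data; filter first")
  if (any(is.na(g$variants$aa)))
    abort("sites without ancestral state present; filter first")
  if (is.null(genome_length)) genome_length <- attr(g, "genome_length")
  pops <- split(seq_len(nrow(g$samples)), g$samples$pop)
  missing_pop <- setdiff(panel$pop, names(pops))
  if (length(missing_pop))
    abort(paste("panel populations absent from genotypes:",
                paste(missing_pop, collapse = ", ")))
  dims <- panel$haploids + 1L
  k <- nrow(panel)
  derived <- matrix(0L, ncol = k, nrow = n_sites(g))
  for (j in seq_len(k)) {
    rows <- pops[[panel$pop[j]]]
    if (2L * length(rows) != panel$haploids[j])
      abort(paste0("panel haploid size mismatch for ", panel$pop[j]))
    derived[, j] <- colSums(g$calls[rows, , drop = FALSE])
  }
  lin <- sfs_linear_index(derived, dims)
  counts <- array(tabulate(lin, nbins = prod(dims)), dim = dims)
  mono <- counts[1]
  counts[1] <- 0L
  if (!is.null(genome_length))
    mono <- mono + max(0, genome_length - n_sites(g))
  joint_sfs(panel, counts, monomorphic = mono)
}

#' Mask low-count SFS entries
#'
#' Marks entries whose counts do not exceed `min_count` as excluded from
#' parameter estimation (counts are left untouched).  With the default
#' `min_count = 5` only entries with counts strictly greater than 5 are
#' retained, guarding the composite likelihood against sparsely observed
#' cells.
#'
#' @param s a `joint_sfs`.
#' @param min_count retain entries with `count > min_count`.
#' @return the `joint_sfs` with its `mask` set.
#' @export
mask_low_count_entries <- function(s, min_count = 5) {
  s$mask <- s$counts <= min_count
  s$mask[1] <- TRUE  # all-ancestral corner lives in `monomorphic`
  attr(s$mask, "min_count") <- min_count
  s
}

#' Marginal SFS for one population
#'
#' Sums the joint SFS over all other axes; equals the one-population SFS
#' built directly.
#'
#' @param s a `joint_sfs`.
#' @param pop population name.
#' @return numeric vector of length haploids+1 (index = derived count).
#' @export
marginal_sfs <- function(s, pop) {
  j <- match(pop, s$panel$pop)
  if (is.na(j)) abort(paste0("population '", pop, "' not in panel"))
  apply(s$counts, j, sum)
}

# ---- .obs-style text interchange ---------------------------------------

#' Write a joint SFS as a multidimensional .obs text file
#'
#' Layout (documented, fastsimcoal-flavoured): a header line, a line with
#' the number of demes and the haploid sample sizes, then the full array
#' flattened with the first population's axis fastest; the all-ancestral
#' corner carries the monomorphic count.  Integer counts are written
#' bit-exactly.
#'
#' @param s a `joint_sfs`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_obs_sfs <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("1 observations. No. of demes and sample sizes are on next line", con)
  writeLines(paste(c(nrow(s$panel), s$panel$haploids), collapse = "\t"), con)
  writeLines(paste(s$panel$pop, collapse = "\t"), con)
  v <- as.vector(s$counts)
  v[1] <- s$monomorphic
  writeLines(paste(format(v, scientific = FALSE, trim = TRUE),
                   collapse = "\t"), con)
  invisible(path)
}

#' Read a joint SFS from a multidimensional .obs text file
#' @param path file written by [write_obs_sfs()].
#' @return a `joint_sfs`.
#' @export
read_obs_sfs <- function(path) {
  ln <- readLines(path)
  hdr <- as.numeric(strsplit(ln[2], "\\s+")[[1]])
  k <- hdr[1]
  haploids <- as.integer(hdr[1 + seq_len(k)])
  pops <- strsplit(ln[3], "\\s+")[[1]]
  v <- as.numeric(strsplit(trimws(ln[4]), "\\s+")[[1]])
  panel <- population_panel(pops, haploids)
  mono <- v[1]; v[1] <- 0
  joint_sfs(panel, v, monomorphic = mono)
}

# ---- genomic blocks and block bootstrap --------------------------------

#' Partition sites into contiguous genomic blocks
#'
#' Blocks are fixed spans (default 1 Mb) measured from the start of each
#' chromosome; trailing partial blocks are kept.  Every site belongs to
#' exactly one block.
#'
#' @param g a `geno_matrix`.
#' @param span_bp nominal block span in bp.
#' @return an object of class `block_index`: list with `blocks` (tibble
#'   `block`, `chrom`, `start`, `end`, `n_sites`) and `site_block` (block id
#'   per site of `g`).
#' @export
make_blocks <- function(g, span_bp = 1e6) {
  v <- g$variants
  key <- paste(v$chrom, (v$pos - 1) %/% span_bp, sep = ":")
  ids <- match(key, unique(key))
  blocks <- tibble(chrom = v$chrom, bin = (v$pos - 1) %/% span_bp,
                   block = ids) |>
    distinct(.data$block, .data$chrom, .data$bin) |>
    mutate(start = .data$bin * span_bp + 1, end = (.data$bin + 1) * span_bp) |>
    select("block", "chrom", "start", "end")
  blocks$n_sites <- as.integer(table(factor(ids, levels = blocks$block)))
  structure(list(blocks = blocks, site_block = ids, span_bp = span_bp),
            class = "block_index")
}

#' Block-bootstrap joint SFS replicates
#'
#' Each replicate resamples the original number of genomic blocks with
#' replacement and rebuilds the SFS from the concatenated blocks, keeping
#' the total block count fixed.  Monomorphic mass beyond the polymorphic
#' sites (when `g` carries a `genome_length`) is reallocated proportionally
#' to the resampled block spans.
#'
#' @param g filtered `geno_matrix`.
#' @param panel a [population_panel()].
#' @param blocks a [make_blocks()] index covering all sites of `g`.
#' @param n_boot number of replicates (>= 1).
#' @param seed integer seed; the replicate sequence is deterministic.
#' @return list of `joint_sfs`, one per replicate.
#' @export
bootstrap_sfs <- function(g, panel, blocks, n_boot, seed = 1) {
  if (n_boot < 1) abort("n_boot must be >= 1")
  base <- build_joint_sfs(g, panel, genome_length = NULL)
  dims <- dim(base$counts)
  nb <- nrow(blocks$blocks)
  # per-block cell tallies (rows = cells present anywhere, sparse-ish)
  pops <- split(seq_len(nrow(g$samples)), g$samples$pop)
  k <- nrow(panel)
  derived <- matrix(0L, ncol = k, nrow = n_sites(g))
  for (j in seq_len(k))
    derived[, j] <- colSums(g$calls[pops[[panel$pop[j]]], , drop = FALSE])
  lin <- sfs_linear_index(derived, dims)
  per_block <- lapply(seq_len(nb), function(b)
    tabulate(lin[blocks$site_block == b], nbins = prod(dims)))
  genome_length <- attr(g, "genome_length")
  extra_mono <- if (is.null(genome_length)) 0 else
    max(0, genome_length - n_sites(g))
  bp <- blocks$blocks$end - blocks$blocks$start + 1
  mono_block <- extra_mono * bp / sum(bp)
  rng <- make_rng(seed)
  lapply(seq_len(n_boot), function(i) {
    draw <- floor(rng(nb) * nb) + 1
    cnt <- Reduce(`+`, per_block[draw])
    cnt <- array(cnt, dim = dims)
    mono <- cnt[1] + sum(mono_block[draw])
    cnt[1] <- 0
    joint_sfs(panel, cnt, monomorphic = mono)
  })
}

# Deterministic uniform generator independent of the global RNG state.
make_rng <- function(seed) {
  env <- new.env()
  env$state <- as.double((seed %% 2147483647) + 1)
  function(n) {
    out <- numeric(n)
    s <- env$state
    for (i in seq_len(n)) {
      s <- (s * 16807) %% 2147483647  # Lehmer MINSTD
      out[i] <- s / 2147483647
    }
    env$state <- s
    out
  }
}

#' Fold a joint SFS (minor-allele orientation)
#'
#' Adds each cell to its complementary cell (derived counts replaced by
#' haploids minus derived), keeping whichever orientation has the smaller
#' total derived count; used when ancestral states are unavailable.  The
#' unfolded spectrum remains the package's default mode, since the site
#' filters guarantee ancestral information.
#'
#' @param s a `joint_sfs` with integer counts.
#' @return a `joint_sfs` with counts folded onto minor-allele cells and a
#'   `folded` attribute set.
#' @export
fold_joint_sfs <- function(s) {
  dims <- dim(s$counts)
  total <- sum(s$panel$haploids)
  out <- array(0, dim = dims)
  idx <- arrayInd(seq_along(s$counts), dims) - 1L
  derived_tot <- rowSums(idx)
  comp <- sweep(-idx, 2, s$panel$haploids, `+`)
  comp_lin <- sfs_linear_index(comp, dims)
  for (i in seq_along(s$counts)) {
    v <- s$counts[i]
    if (v == 0) next
    j <- if (derived_tot[i] * 2 > total) comp_lin[i] else i
    out[j] <- out[j] + v
  }
  s$counts <- out
  attr(s, "folded") <- TRUE
  s
}
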