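#' Diploid genotype matrices with ancestral-allele polarity
#'
#' The substrate for SFS and f-statistic analyses: per-sample population
#' labels, per-site variant metadata (including the ancestral allele where
#' known) and a samples x sites matrix of diploid genotypes.  When the
#' ancestral allele is known, calls count derived-allele copies (0/1/2);
#' at sites with unknown ancestral state they count alternate-allele copies
#' and are only usable after filtering.  `NA` marks missing calls.
#'
#' @param samples tibble with columns `sample_id`, `pop`.
#' @param variants tibble with columns `chrom`, `pos`, `ref`, `alt`, `aa`
#'   (ancestral allele, `NA` if unknown); optional logical `cpg`, `coding`.
#' @param calls integer matrix, `nrow(samples)` x `nrow(variants)`.
#' @param genome_length optional number of callable sites the variants come
#'   from (used for monomorphic bookkeeping downstream).
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(samples, variants, calls, genome_length = NULL) {
  samples <- as_tibble(samples)
  variants <- as_tibble(variants)
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(variants))
    abort("calls must be n_samples x n_sites")
  if (!"cpg" %in% names(variants)) variants$cpg <- FALSE
  if (!"coding" %in% names(variants)) variants$coding <- FALSE
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      abort(paste0("positions not strictly increasing on ", ch))
  }
  g <- structure(list(samples = samples, variants = variants, calls = calls),
                 class = "geno_matrix")
  attr(g, "genome_length") <- genome_length
  g
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$samples), " samples x ", ncol(x$calls),
      " sites; populations: ",
      paste(unique(x$samples$pop), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param g a `geno_matrix`.
#' @return integer count.
#' @export
n_sites <- function(g) ncol(g$calls)

#' @rdname n_sites
#' @export
n_samples <- function(g) nrow(g$calls)

#' Subset a genotype matrix by site index
#' @param g a `geno_matrix`.
#' @param sites integer or logical site index.
#' @return a `geno_matrix` restricted to `sites`.
#' @export
subset_sites <- function(g, sites) {
  out <- geno_matrix(g$samples, g$variants[sites, , drop = FALSE],
                     g$calls[, sites, drop = FALSE],
                     genome_length = attr(g, "genome_length"))
  attr(out, "removals") <- attr(g, "removals")
  out
}

# ---- reading and writing ------------------------------------------------

#' Read a genotype panel from VCF or EIGENSTRAT files
#'
#' Only biallelic SNPs are retained; multi-allelic and indel records are
#' dropped with a logged count.  The ancestral allele is taken from the
#' `AA` INFO field (VCF) or a seventh column of the `.snp` file
#' (EIGENSTRAT); records whose ancestral allele matches neither REF nor ALT
#' are treated as unknown.  Calls are polarized to derived-allele counts
#' whenever the ancestral allele is known.
#'
#' @param path VCF file, or the common prefix of an EIGENSTRAT
#'   `.geno`/`.snp`/`.ind` triplet.
#' @param format `"vcf"` or `"eigenstrat"`.
#' @param pop_map optional named character vector mapping sample id to
#'   population (VCF carries no population labels; defaults to `"pop1"`).
#' @return a `geno_matrix`.
#' @export
read_genotypes <- function(path, format = c("vcf", "eigenstrat"),
                           pop_map = NULL) {
  format <- match.arg(format)
  if (format == "vcf") read_genotypes_vcf(path, pop_map)
  else read_genotypes_eigenstrat(path, pop_map)
}

read_genotypes_vcf <- function(path, pop_map) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  samples <- colnames(vcf@gt)[-1]
  if (n_in == 0) {
    return(geno_matrix(
      samples = tibble(sample_id = samples,
                       pop = pop_label(samples, pop_map)),
      variants = tibble(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        aa = character()),
      calls = matrix(integer(), nrow = length(samples), ncol = 0)))
  }
  snp <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_drop <- sum(!snp)
  if (n_drop > 0)
    message(n_drop, " multi-allelic/indel record(s) dropped")
  aa <- toupper(vcfR::extract.info(vcf, "AA"))
  gt <- vcfR::extract.gt(vcf)
  fix <- fix[snp, , drop = FALSE]
  aa <- aa[snp]
  gt <- gt[snp, , drop = FALSE]
  aa[!(aa == fix$REF | aa == fix$ALT) | is.na(aa)] <- NA
  alt_count <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  core <- gsub("\\|", "/", substr(gt, 1, 3))
  alt_count[core == "0/0"] <- 0L
  alt_count[core %in% c("0/1", "1/0")] <- 1L
  alt_count[core == "1/1"] <- 2L
  # polarize: derived counts where ancestral allele is known
  flip <- !is.na(aa) & aa == fix$ALT
  alt_count[flip, ] <- 2L - alt_count[flip, , drop = FALSE]
  geno_matrix(
    samples = tibble(sample_id = samples, pop = pop_label(samples, pop_map)),
    variants = tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, aa = aa),
    calls = t(alt_count))
}

pop_label <- function(samples, pop_map) {
  if (is.null(pop_map)) return(rep("pop1", length(samples)))
  if (!all(samples %in% names(pop_map)))
    abort("pop_map does not cover all samples")
  unname(pop_map[samples])
}

read_genotypes_eigenstrat <- function(prefix, pop_map) {
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  for (p in paths) if (!file.exists(p)) abort(paste0("no such file: ", p))
  ind <- utils::read.table(paths[3], header = FALSE,
                           col.names = c("sample_id", "sex", "pop"),
                           stringsAsFactors = FALSE)
  snp <- utils::read.table(paths[2], header = FALSE, fill = TRUE,
                           stringsAsFactors = FALSE)
  names(snp)[1:6] <- c("id", "chrom", "gpos", "pos", "ref", "alt")
  aa <- if (ncol(snp) >= 7) toupper(snp[[7]]) else rep(NA_character_, nrow(snp))
  aa[aa %in% c("", ".", "N", "X")] <- NA
  aa[!is.na(aa) & !(aa == snp$ref | aa == snp$alt)] <- NA
  lines <- readLines(paths[1])
  if (length(lines) != nrow(snp))
    abort("geno/snp line count mismatch")
  calls <- matrix(NA_integer_, nrow = nrow(ind), ncol = nrow(snp))
  for (s in seq_along(lines)) {
    digs <- as.integer(strsplit(lines[s], "")[[1]])
    if (length(digs) != nrow(ind))
      abort(paste0("geno line ", s, " has wrong sample count"))
    digs[digs == 9L] <- NA_integer_
    calls[, s] <- digs
  }
  pops <- if (is.null(pop_map)) ind$pop else pop_label(ind$sample_id, pop_map)
  geno_matrix(samples = tibble(sample_id = ind$sample_id, pop = pops),
              variants = tibble(chrom = as.character(snp$chrom),
                                pos = as.integer(snp$pos),
                                ref = snp$ref, alt = snp$alt, aa = aa),
              calls = calls)
}

#' Write a genotype panel to VCF or EIGENSTRAT files
#'
#' Inverse of [read_genotypes()]: a written panel reads back with an
#' identical calls matrix.  The VCF writer emits a plain-text v4.2 file
#' with the ancestral allele in the `AA` INFO field; the EIGENSTRAT writer
#' emits a geno/snp/ind triplet with the ancestral allele as a seventh
#' `.snp` column.
#'
#' @param g a `geno_matrix`.
#' @param path output VCF file, or EIGENSTRAT prefix.
#' @param format `"vcf"` or `"eigenstrat"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "eigenstrat")) {
  format <- match.arg(format)
  if (format == "vcf") write_genotypes_vcf(g, path)
  else write_genotypes_eigenstrat(g, path)
  invisible(path)
}

write_genotypes_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples$sample_id),
                     collapse = "\t")), con)
  if (n_sites(g) == 0) return()
  v <- g$variants
  # de-polarize back to alternate-allele dosage
  alt_count <- t(g$calls)
  flip <- !is.na(v$aa) & v$aa == v$alt
  alt_count[flip, ] <- 2L - alt_count[flip, , drop = FALSE]
  gt <- matrix("./.", nrow = nrow(alt_count), ncol = ncol(alt_count))
  gt[!is.na(alt_count) & alt_count == 0L] <- "0/0"
  gt[!is.na(alt_count) & alt_count == 1L] <- "0/1"
  gt[!is.na(alt_count) & alt_count == 2L] <- "1/1"
  info <- ifelse(is.na(v$aa), "AA=.", paste0("AA=", v$aa))
  rows <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(rows, con)
}

write_genotypes_eigenstrat <- function(g, prefix) {
  utils::write.table(
    data.frame(g$samples$sample_id, "U", g$samples$pop),
    paste0(prefix, ".ind"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
  v <- g$variants
  utils::write.table(
    data.frame(paste0(v$chrom, "_", v$pos), v$chrom, 0, v$pos, v$ref, v$alt,
               ifelse(is.na(v$aa), ".", v$aa)),
    paste0(prefix, ".snp"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
  m <- g$calls
  m[is.na(m)] <- 9L
  writeLines(apply(m, 2, paste, collapse = ""), paste0(prefix, ".geno"))
}

# ---- interval masks -----------------------------------------------------

#' Read a BED interval file
#' @param path 3+ column BED file (half-open, 0-based).
#' @return tibble with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  tibble(chrom = as.character(bed[[1]]), start = as.numeric(bed[[2]]),
         end = as.numeric(bed[[3]]))
}

# TRUE for each (chrom, pos) falling inside the (merged) interval set;
# BED half-open 0-based, positions 1-based.
in_intervals <- function(chrom, pos, bed) {
  if (is.null(bed) || nrow(bed) == 0) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (ch in unique(bed$chrom)) {
    iv <- bed[bed$chrom == ch, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    # merge overlaps
    keep_s <- numeric(); keep_e <- numeric()
    for (i in seq_len(nrow(iv))) {
      if (length(keep_s) && iv$start[i] <= keep_e[length(keep_e)]) {
        keep_e[length(keep_e)] <- max(keep_e[length(keep_e)], iv$end[i])
      } else {
        keep_s <- c(keep_s, iv$start[i]); keep_e <- c(keep_e, iv$end[i])
      }
    }
    sel <- chrom == ch
    z <- pos[sel] - 1  # to 0-based
    j <- findInterval(z, keep_s)
    hit[sel] <- j >= 1 & z < keep_e[pmax(j, 1)]
  }
  hit
}

# ---- SFS site filters ---------------------------------------------------

#' Apply the SFS site filters
#'
#' Removes sites that are (i) missing in at least one sample, (ii) out of
#' Hardy-Weinberg equilibrium (exact test, p < `hwe_alpha`) in at least one
#' population, (iii) inside the CpG mask, (iv) inside the coding mask, or
#' (v) lacking ancestral-state information.  Filtering is idempotent.  The
#' per-criterion removal counts (a site may fail several criteria) are
#' attached as the `"removals"` attribute and retrievable with
#' [filter_report()].
#'
#' @param g a `geno_matrix`.
#' @param hwe_alpha HWE exact-test threshold (default 1e-4).
#' @param cpg_mask,coding_mask BED interval tibbles (`chrom`, `start`,
#'   `end`), as from [read_bed()]; if `NULL`, the per-variant `cpg`/`coding`
#'   flags are used instead.
#' @param per_population test HWE within each population (default) or
#'   across all samples pooled.
#' @return the filtered `geno_matrix`.
#' @export
apply_sfs_filters <- function(g, hwe_alpha = 1e-4, cpg_mask = NULL,
                              coding_mask = NULL, per_population = TRUE) {
  S <- n_sites(g)
  miss <- apply(g$calls, 2, anyNA)
  groups <- if (per_population) split(seq_len(nrow(g$samples)), g$samples$pop)
            else list(all = seq_len(nrow(g$samples)))
  if (any(vapply(groups, length, 1L) == 0)) abort("empty population")
  hwe_fail <- rep(FALSE, S)
  for (rows in groups) {
    sub <- g$calls[rows, , drop = FALSE]
    n_het <- colSums(sub == 1L, na.rm = TRUE)
    n_ref <- colSums(sub == 0L, na.rm = TRUE)
    n_alt <- colSums(sub == 2L, na.rm = TRUE)
    p <- vapply(seq_len(S), function(s)
      hwe_exact_p(n_het[s], n_ref[s], n_alt[s]), numeric(1))
    hwe_fail <- hwe_fail | (p < hwe_alpha)
  }
  cpg <- if (is.null(cpg_mask)) g$variants$cpg
         else in_intervals(g$variants$chrom, g$variants$pos, cpg_mask)
  cod <- if (is.null(coding_mask)) g$variants$coding
         else in_intervals(g$variants$chrom, g$variants$pos, coding_mask)
  no_aa <- is.na(g$variants$aa)
  removals <- tibble(
    criterion = c("missing", "hwe", "cpg", "coding", "no_ancestral"),
    n_removed = c(sum(miss), sum(hwe_fail), sum(cpg), sum(cod), sum(no_aa)))
  keep <- !(miss | hwe_fail | cpg | cod | no_aa)
  out <- subset_sites(g, keep)
  attr(out, "removals") <- removals
  out
}

#' Per-criterion removal counts from the last filtering
#' @param g a `geno_matrix` returned by [apply_sfs_filters()].
#' @return tibble with `criterion`, `n_removed`.
#' @export
filter_report <- function(g) {
  rem <- attr(g, "removals")
  if (is.null(rem)) abort("no filter report attached; run apply_sfs_filters()")
  rem
}

# ---- allele frequencies -------------------------------------------------

#' Per-population derived-allele frequencies
#'
#' @param g a `geno_matrix`.
#' @param panel a [population_panel()]; every sample of `g` must belong to
#'   a panel population.
#' @return a `freq_panel`: list with `freq` (sites x pops matrix; `NA`
#'   where a population has no non-missing calls), `n_obs` (non-missing
#'   allele counts, same shape) and `sites` (tibble `chrom`, `pos`).
#' @export
allele_frequencies <- function(g, panel) {
  extra <- setdiff(g$samples$pop, panel$pop)
  if (length(extra))
    abort(paste("samples assigned to populations outside the panel:",
                paste(extra, collapse = ", ")))
  k <- nrow(panel)
  S <- n_sites(g)
  freq <- matrix(NA_real_, S, k, dimnames = list(NULL, panel$pop))
  nobs <- matrix(0L, S, k, dimnames = list(NULL, panel$pop))
  for (j in seq_len(k)) {
    rows <- which(g$samples$pop == panel$pop[j])
    sub <- g$calls[rows, , drop = FALSE]
    nn <- 2L * colSums(!is.na(sub))
    dd <- colSums(sub, na.rm = TRUE)
    freq[, j] <- ifelse(nn > 0, dd / nn, NA_real_)
    nobs[, j] <- nn
  }
  freq_panel(freq, nobs, g$variants[, c("chrom", "pos")])
}

#' Construct an allele-frequency panel
#' @param freq sites x populations matrix of derived-allele frequencies.
#' @param n_obs matching matrix of observed (non-missing) allele counts.
#' @param sites tibble with `chrom`, `pos` (one row per site).
#' @return an object of class `freq_panel`.
#' @export
freq_panel <- function(freq, n_obs = NULL, sites = NULL) {
  freq <- as.matrix(freq)
  if (is.null(n_obs)) n_obs <- matrix(Inf, nrow(freq), ncol(freq),
                                      dimnames = dimnames(freq))
  if (is.null(sites)) sites <- tibble(chrom = "1", pos = seq_len(nrow(freq)))
  structure(list(freq = freq, n_obs = as.matrix(n_obs),
                 sites = as_tibble(sites)),
            class = "freq_panel")
}

#' @export
print.freq_panel <- function(x, ...) {
  cat("<freq_panel> ", nrow(x$freq), " sites x ", ncol(x$freq),
      " populations: ", paste(colnames(x$freq), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.freq_panel <- function(x, ...) {
  bind_cols(x$sites[rep(seq_len(nrow(x$freq)), ncol(x$freq)), ],
            tibble(pop = rep(colnames(x$freq), each = nrow(x$freq)),
                   freq = as.vector(x$freq),
                   n_obs = as.vector(x$n_obs)))
}

# ---- kinship ------------------------------------------------------------

#' Pairwise genotype mismatch rate
#'
#' Fraction of jointly non-missing sites at which two samples carry
#' different unordered diploid genotypes.  Used for kinship screening:
#' identical twins/duplicates approach the genotyping error rate, and
#' first/second-degree relative pairs sit well below the unrelated
#' background.
#'
#' @param g a `geno_matrix`.
#' @param i,j sample ids or indices.
#' @return mismatch rate in `[0, 1]`.
#' @export
pairwise_mismatch_rate <- function(g, i, j) {
  ix <- if (is.character(i)) match(i, g$samples$sample_id) else i
  jx <- if (is.character(j)) match(j, g$samples$sample_id) else j
  if (is.na(ix) || is.na(jx)) abort("unknown sample")
  a <- g$calls[ix, ]; b <- g$calls[jx, ]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) abort("no jointly non-missing sites")
  mean(a[ok] != b[ok])
}
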