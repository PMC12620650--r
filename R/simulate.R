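#' Specify a coalescent simulation
#'
#' Couples a demographic model with parameter values, per-population sample
#' sizes and either a number of independent genealogy replicates (for
#' expected spectra) or a sequence length in bp (for genotype panels).
#'
#' @param model a `demog_model` (free parameters allowed).
#' @param params named values for the model's free parameters.
#' @param sample_sizes named vector of diploid sample sizes per population.
#' @param n_reps number of genealogy replicates for [expected_sfs()].
#' @param length sequence length in bp for [simulate_genotypes()].
#' @param seed integer seed; all simulation output is deterministic in it.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(model, params = NULL, sample_sizes, n_reps = NULL,
                     length = NULL, seed = 1) {
  if (any(sample_sizes < 1)) abort("sample sizes must be >= 1")
  if (is.null(n_reps) && is.null(length))
    abort("one of n_reps or length must be set")
  if (!is.null(n_reps) && n_reps <= 0) abort("n_reps must be positive")
  if (!is.null(length) && length <= 0) abort("length must be positive")
  structure(list(model = model, params = params,
                 sample_sizes = sample_sizes, n_reps = n_reps,
                 length = length, seed = seed),
            class = "sim_spec")
}

# bind + flatten a spec; returns flattened model + panel in model pop order
spec_flatten <- function(spec) {
  bound <- bind_params(spec$model, spec$params)
  ss <- spec$sample_sizes
  ord <- intersect(bound$populations$name, names(ss))
  if (length(ord) != length(ss))
    abort("sample_sizes name populations absent from the model")
  ss <- ss[ord]
  fl <- flatten_model(bound, setNames(2L * as.integer(ss), ord))
  panel <- population_panel(ord, 2L * as.integer(ss))
  list(fl = fl, panel = panel, bound = bound)
}

#' Monte-Carlo expected joint SFS
#'
#' Simulates independent single-locus genealogies under the model and
#' converts mean branch lengths per derived-count configuration into
#' per-site probabilities: a cell's probability is mu times the expected
#' branch length subtending that configuration, and the monomorphic
#' probability is the complement, so all cells (monomorphic included) sum
#' to one.
#'
#' @param spec a [sim_spec()] with `n_reps` set.
#' @return a `joint_sfs` of kind `"expected"` whose `counts` hold cell
#'   probabilities and `monomorphic` the monomorphic probability.
#' @export
expected_sfs <- function(spec) {
  sf <- spec_flatten(spec)
  res <- sim_expected_sfs_cpp(sf$fl$n_pops, sf$fl$samp, sf$fl$init,
                              sf$fl$events, as.integer(spec$n_reps),
                              spec$seed)
  mu <- sf$bound$mu
  p <- res$cell_len * mu
  tot <- res$total_len * mu
  if (tot >= 1)
    warn("mu * expected tree length >= 1; model violates the rare-mutation regime")
  p[1] <- 0
  joint_sfs(sf$panel, p, monomorphic = max(0, 1 - sum(p)), kind = "expected")
}

#' Simulate a diploid genotype panel
#'
#' Splits the requested sequence length into independent loci (one
#' genealogy each), drops Poisson mutations on branches proportionally to
#' length, and emits polarized diploid genotypes with fully known ancestral
#' alleles and no missingness, on a single synthetic chromosome.
#'
#' @param spec a [sim_spec()] with `length` set (bp).
#' @param bp_per_locus locus size in bp (default 500); loci are
#'   statistically independent.
#' @return a `geno_matrix` with a `genome_length` attribute equal to
#'   `spec$length`.
#' @export
simulate_genotypes <- function(spec, bp_per_locus = 500) {
  if (is.null(spec$length)) abort("spec$length (sequence length) must be set")
  sf <- spec_flatten(spec)
  n_loci <- as.integer(ceiling(spec$length / bp_per_locus))
  res <- sim_sites_cpp(sf$fl$n_pops, sf$fl$samp, sf$fl$init, sf$fl$events,
                       n_loci, bp_per_locus, sf$bound$mu, spec$seed)
  carriers <- res$carriers
  pos <- as.integer((res$locus - 1) * bp_per_locus +
                    floor(res$offset * bp_per_locus) + 1)
  ord <- order(pos)
  ord <- ord[!duplicated(pos[ord])]  # drop rare position collisions
  carriers <- carriers[, ord, drop = FALSE]
  pos <- pos[ord]
  # haploids are pop-major in panel order; fold into diploids
  dip <- sf$panel$haploids %/% 2L
  calls <- carriers[seq(1, nrow(carriers), by = 2), , drop = FALSE] +
    carriers[seq(2, nrow(carriers), by = 2), , drop = FALSE]
  samples <- tibble(
    sample_id = unlist(lapply(seq_len(nrow(sf$panel)), function(j)
      paste0(sf$panel$pop[j], "_", seq_len(dip[j])))),
    pop = rep(sf$panel$pop, dip))
  variants <- tibble(chrom = "1", pos = pos,
                     ref = "A", alt = "G", aa = "A")
  geno_matrix(samples, variants, calls, genome_length = spec$length)
}

# ---- allele-frequency drift simulator ----------------------------------

#' Simulate a multi-population allele-frequency panel with drift and
#' admixture
#'
#' Frequencies start at a root value per site, drift along each branch of a
#' population tree by a Balding-Nichols beta update of magnitude `f`, and
#' admixed nodes are formed as a weighted mixture of already-simulated
#' node frequencies before applying their own terminal drift.  Optionally,
#' finite samples of alleles are drawn per population so downstream
#' statistics can apply finite-sample corrections.
#'
#' @param nodes tibble with columns `name`, `parent` (`NA` for the root),
#'   `f` (drift magnitude along the branch into the node, 0 = none) and
#'   optionally `mix` (list column: named numeric mixing weights over other
#'   node names, summing to 1; weights must lie in `[0, 1]`).
#' @param n_sites number of independent sites.
#' @param sample_n named vector of sampled allele counts (haploid) per
#'   emitted population; nodes not named are treated as latent.  If `NULL`,
#'   all leaf nodes are emitted with their exact frequencies.
#' @param root_range range of the uniform root-frequency distribution.
#' @param seed integer seed.
#' @return a `freq_panel`; the generating node frequencies are attached as
#'   attribute `"truth_freq"`.
#' @export
simulate_freq_panel <- function(nodes, n_sites, sample_n = NULL,
                                root_range = c(0.05, 0.95), seed = 1) {
  nodes <- as_tibble(nodes)
  if (!"mix" %in% names(nodes)) nodes$mix <- vector("list", nrow(nodes))
  for (m in nodes$mix) {
    if (!is.null(m)) {
      if (any(m < 0 | m > 1)) abort("mixture weights must lie in [0, 1]")
      if (abs(sum(m) - 1) > 1e-8) abort("mixture weights must sum to 1")
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  P <- matrix(NA_real_, n_sites, nrow(nodes),
              dimnames = list(NULL, nodes$name))
  bn_drift <- function(p, f) {
    if (f <= 0) return(p)
    a <- p * (1 - f) / f
    b <- (1 - p) * (1 - f) / f
    q <- rbeta(length(p), pmax(a, 1e-12), pmax(b, 1e-12))
    # beta draws can hit the boundary numerically; keep in closed [0,1]
    pmin(pmax(q, 0), 1)
  }
  done <- rep(FALSE, nrow(nodes))
  while (!all(done)) {
    progressed <- FALSE
    for (i in seq_len(nrow(nodes))) {
      if (done[i]) next
      mx <- nodes$mix[[i]]
      if (!is.null(mx)) {
        deps <- names(mx)
        if (!all(deps %in% nodes$name[done])) next
        base <- as.matrix(P[, deps, drop = FALSE]) %*% as.numeric(mx)
        P[, i] <- bn_drift(as.vector(base), nodes$f[i])
      } else if (is.na(nodes$parent[i])) {
        P[, i] <- runif(n_sites, root_range[1], root_range[2])
        P[, i] <- bn_drift(P[, i], nodes$f[i])
      } else {
        if (!done[match(nodes$parent[i], nodes$name)]) next
        P[, i] <- bn_drift(P[, nodes$parent[i]], nodes$f[i])
      }
      done[i] <- TRUE; progressed <- TRUE
    }
    if (!progressed) abort("node dependency cycle (check parent/mix columns)")
  }
  if (is.null(sample_n)) {
    leaves <- setdiff(nodes$name, nodes$parent)
    out <- freq_panel(P[, leaves, drop = FALSE])
  } else {
    emit <- names(sample_n)
    Fq <- matrix(NA_real_, n_sites, length(emit), dimnames = list(NULL, emit))
    Nm <- matrix(0L, n_sites, length(emit), dimnames = list(NULL, emit))
    for (j in seq_along(emit)) {
      n <- sample_n[[j]]
      Fq[, j] <- rbinom(n_sites, n, P[, emit[j]]) / n
      Nm[, j] <- n
    }
    out <- freq_panel(Fq, Nm)
  }
  attr(out, "truth_freq") <- P
  out
}
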