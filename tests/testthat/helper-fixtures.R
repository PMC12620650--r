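# small in-code fixtures shared across tests

# deterministic toy genotype matrix: 2 populations x 3 diploids, 8 sites
toy_geno <- function() {
  samples <- tibble::tibble(
    sample_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    pop = rep(c("A", "B"), each = 3))
  variants <- tibble::tibble(
    chrom = "1",
    pos = c(100L, 200L, 300L, 400L, 500L, 600L, 700L, 800L),
    ref = "A", alt = "G",
    aa = c("A", "A", "A", "G", "A", "A", "A", "A"))
  calls <- matrix(0L, 6, 8)
  calls[, 2] <- c(1L, 0L, 0L, 0L, 1L, 2L)
  calls[, 3] <- c(2L, 2L, 2L, 2L, 2L, 2L)
  calls[, 4] <- c(0L, 1L, 0L, 1L, 0L, 0L)
  calls[, 5] <- c(0L, 0L, 1L, 1L, 1L, 1L)
  calls[1, 6] <- NA
  calls[, 7] <- c(0L, 2L, 0L, 0L, 0L, 2L)
  geno_matrix(samples, variants, calls)
}

# random genotype matrix with known seed (no missing, ancestral known)
random_geno <- function(n_per_pop = 3, n_sites = 50, seed = 42,
                        pops = c("A", "B")) {
  set.seed(seed)
  n <- n_per_pop * length(pops)
  samples <- tibble::tibble(
    sample_id = paste0(rep(pops, each = n_per_pop), seq_len(n_per_pop)),
    pop = rep(pops, each = n_per_pop))
  variants <- tibble::tibble(
    chrom = "1", pos = sort(sample.int(1e6, n_sites)),
    ref = "A", alt = "G", aa = "A")
  calls <- matrix(sample(0:2, n * n_sites, replace = TRUE,
                         prob = c(0.6, 0.3, 0.1)), n, n_sites)
  geno_matrix(samples, variants, calls)
}

# single constant-size population model
one_pop_model <- function(ne = 1e4) {
  demog_model(
    populations = tibble::tibble(name = "A", size = ne),
    splits = tibble::tibble(time = numeric(), derived = character(),
                            ancestral = character(), size = numeric()))
}

# two populations splitting at time t
two_pop_model <- function(t = 200, ne = 1e4) {
  demog_model(
    populations = tibble::tibble(name = c("A", "B"), size = ne),
    splits = tibble::tibble(time = t, derived = "B", ancestral = "A",
                            size = ne))
}
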