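test_that("joint SFS matches brute-force per-site tallying", {
  g <- random_geno(n_per_pop = 2, n_sites = 60, seed = 3)
  panel <- population_panel(c("A", "B"), c(4, 4))
  s <- build_joint_sfs(g, panel)
  # brute force: count each (dA, dB) combination by looping sites
  brute <- array(0, c(5, 5))
  for (i in seq_len(n_sites(g))) {
    da <- sum(g$calls[1:2, i])
    db <- sum(g$calls[3:4, i])
    brute[da + 1, db + 1] <- brute[da + 1, db + 1] + 1
  }
  mono <- brute[1, 1]
  brute[1, 1] <- 0
  expect_equal(unname(s$counts), brute)
  expect_equal(s$monomorphic, mono)
  expect_equal(sum(s$counts) + s$monomorphic, n_sites(g))
})

test_that("single-site and degenerate spectra", {
  samples <- tibble::tibble(sample_id = c("a1", "b1"), pop = c("A", "B"))
  variants <- tibble::tibble(chrom = "1", pos = 1L, ref = "A", alt = "G",
                             aa = "A")
  g <- geno_matrix(samples, variants, matrix(c(1L, 0L), 2, 1))
  s <- build_joint_sfs(g, population_panel(c("A", "B"), c(2, 2)))
  expect_equal(s$counts[2, 1], 1)
  expect_equal(sum(s$counts), 1)
  # all monomorphic-ancestral
  g0 <- geno_matrix(samples, variants, matrix(c(0L, 0L), 2, 1))
  s0 <- build_joint_sfs(g0, population_panel(c("A", "B"), c(2, 2)))
  expect_equal(sum(s0$counts), 0)
  expect_equal(s0$monomorphic, 1)
})

test_that("marginalizing a 2-pop joint SFS equals the 1-pop SFS", {
  g <- random_geno(n_per_pop = 3, n_sites = 80, seed = 9)
  panel2 <- population_panel(c("A", "B"), c(6, 6))
  s2 <- build_joint_sfs(g, panel2)
  gA <- geno_matrix(g$samples[1:3, ], g$variants, g$calls[1:3, , drop = FALSE])
  sA <- build_joint_sfs(gA, population_panel("A", 6))
  mA <- marginal_sfs(s2, "A")
  direct <- as.vector(sA$counts)
  direct[1] <- sA$monomorphic
  got <- mA
  got[1] <- got[1] + s2$monomorphic
  expect_equal(got, direct)
})

test_that("panel reordering permutes the SFS axes", {
  g <- random_geno(n_per_pop = 2, n_sites = 60, seed = 21)
  sAB <- build_joint_sfs(g, population_panel(c("A", "B"), c(4, 4)))
  sBA <- build_joint_sfs(g, population_panel(c("B", "A"), c(4, 4)))
  expect_equal(unname(sBA$counts), unname(aperm(sAB$counts, c(2, 1))))
})

test_that("low-count masking thresholds are strict", {
  panel <- population_panel("A", 4)
  s <- joint_sfs(panel, c(0, 5, 6, 2, 0))
  s <- mask_low_count_entries(s, 5)
  expect_true(s$mask[2])    # count 5 -> masked
  expect_false(s$mask[3])   # count 6 -> retained
  expect_true(s$mask[4])
  expect_true(s$mask[1])    # corner always excluded
  s0 <- mask_low_count_entries(joint_sfs(panel, c(0, 5, 6, 2, 0)), 0)
  expect_equal(unname(as.vector(s0$mask)), c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # counts unchanged by masking
  expect_equal(as.vector(s0$counts), c(0, 5, 6, 2, 0))
})

test_that(".obs text round trip is bit-exact", {
  g <- random_geno(n_per_pop = 2, n_sites = 100, seed = 33)
  panel <- population_panel(c("A", "B"), c(4, 4))
  s <- build_joint_sfs(g, panel, genome_length = 5000)
  path <- withr::local_tempfile(fileext = ".obs")
  write_obs_sfs(s, path)
  s2 <- read_obs_sfs(path)
  expect_identical(as.vector(s2$counts), as.numeric(as.vector(s$counts)))
  expect_identical(s2$monomorphic, as.numeric(s$monomorphic))
  expect_identical(s2$panel$pop, s$panel$pop)
  expect_identical(s2$panel$haploids, s$panel$haploids)
})

test_that("blocks tile the observed sites exactly once", {
  g <- random_geno(n_per_pop = 2, n_sites = 200, seed = 4)
  g$variants$pos <- sort(sample.int(5e6, 200))
  g$variants$chrom <- rep(c("1", "2"), each = 100)
  g <- geno_matrix(g$samples, g$variants, g$calls)
  bl <- make_blocks(g, span_bp = 1e6)
  expect_equal(length(bl$site_block), n_sites(g))
  expect_true(all(bl$site_block %in% bl$blocks$block))
  expect_equal(sum(bl$blocks$n_sites), n_sites(g))
  # every site inside its block's span
  for (i in seq_len(n_sites(g))) {
    b <- bl$blocks[bl$blocks$block == bl$site_block[i], ]
    expect_true(g$variants$pos[i] >= b$start && g$variants$pos[i] <= b$end)
  }
})

test_that("bootstrap SFS: determinism, forced resample, and expectation", {
  g <- random_geno(n_per_pop = 2, n_sites = 300, seed = 10)
  panel <- population_panel(c("A", "B"), c(4, 4))
  blocks <- make_blocks(g, span_bp = 1e6)
  expect_error(bootstrap_sfs(g, panel, blocks, n_boot = 0), "n_boot")
  b1 <- bootstrap_sfs(g, panel, blocks, n_boot = 5, seed = 99)
  b2 <- bootstrap_sfs(g, panel, blocks, n_boot = 5, seed = 99)
  for (i in 1:5) expect_identical(b1[[i]]$counts, b2[[i]]$counts)
  # one block only -> every replicate equals the original
  g1 <- random_geno(n_per_pop = 2, n_sites = 50, seed = 12)
  g1$variants$pos <- sort(sample.int(9e5, 50))
  g1 <- geno_matrix(g1$samples, g1$variants, g1$calls)
  bl1 <- make_blocks(g1, span_bp = 1e6)
  expect_equal(nrow(bl1$blocks), 1)
  orig <- build_joint_sfs(g1, panel)
  reps <- bootstrap_sfs(g1, panel, bl1, n_boot = 3, seed = 1)
  for (r in reps) expect_equal(unname(r$counts), unname(orig$counts))
  # resampling expectation: mean over replicates approaches the original
  reps <- bootstrap_sfs(g, panel, blocks, n_boot = 1000, seed = 5)
  orig <- build_joint_sfs(g, panel)
  tot <- Reduce(`+`, lapply(reps, function(r) r$counts)) / length(reps)
  big <- orig$counts >= 20
  expect_true(all(abs(tot[big] - orig$counts[big]) / orig$counts[big] < 0.05))
  # sum conservation per replicate: total sites = sum over drawn blocks
  expect_true(all(vapply(reps, function(r)
    sum(r$counts) + r$monomorphic, numeric(1)) %% 1 == 0))
})

test_that("folding maps cells onto minor-allele orientation", {
  panel <- population_panel(c("A", "B"), c(2, 2))
  counts <- array(0, c(3, 3))
  counts[3, 3] <- 4  # derived in all 4 haploids -> folds onto (0,0)... corner
  counts[3, 2] <- 2  # (2,1): 3 of 4 derived -> folds onto (0,1)
  counts[2, 1] <- 7  # (1,0): minor already
  s <- joint_sfs(panel, counts)
  f <- fold_joint_sfs(s)
  expect_equal(f$counts[1, 2], 2)
  expect_equal(f$counts[2, 1], 7)
  expect_equal(f$counts[1, 1], 4)
  expect_equal(sum(f$counts), sum(s$counts))
})

test_that("masked cells can be dropped instead of pooled", {
  panel <- population_panel("A", 4)
  s <- mask_low_count_entries(joint_sfs(panel, c(0, 10, 2, 3, 0)), 5)
  e <- joint_sfs(panel, c(0, 0.5, 0.2, 0.2, 0.1), monomorphic = 0,
                 kind = "expected")
  attr(e, "n_sims") <- 1e6
  ll <- composite_log_likelihood(s, e, include_monomorphic = FALSE,
                                 pool_residual = FALSE)
  # conditioned on the retained support, the only retained cell has
  # probability one
  expect_equal(ll, 10 * log10(0.5 / 0.5), tolerance = 1e-12)
})
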