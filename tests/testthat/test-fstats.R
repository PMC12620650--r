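single_site_panel <- function(freqs) {
  freq_panel(matrix(unlist(freqs), nrow = 1,
                    dimnames = list(NULL, names(freqs))))
}

test_that("f3 and f4 match hand arithmetic on single sites", {
  # duplicate the site across two blocks so the jackknife is defined
  fp <- freq_panel(matrix(rep(c(0.2, 0.4, 0.3), each = 2), nrow = 2,
                          dimnames = list(NULL, c("A", "B", "C"))))
  r3 <- f3(fp, "A", "B", "C", blocks = 2, correct = FALSE)
  expect_equal(r3$estimate, (0.3 - 0.2) * (0.3 - 0.4), tolerance = 1e-12)
  expect_equal(r3$estimate, -0.01)
  fp4 <- freq_panel(matrix(rep(c(0.9, 0.1, 0.8, 0.2), each = 2), nrow = 2,
                           dimnames = list(NULL, c("A", "B", "C", "D"))))
  r4 <- f4(fp4, "A", "B", "C", "D", blocks = 2)
  expect_equal(r4$estimate, 0.8 * 0.6, tolerance = 1e-12)
  expect_equal(r4$estimate, 0.48)
})

test_that("f4 identities: zero at A=B, antisymmetry, pair swap", {
  set.seed(5)
  fr <- matrix(runif(400), 100, 4,
               dimnames = list(NULL, c("A", "B", "C", "D")))
  fr <- cbind(fr, A2 = fr[, "A"])
  fp <- freq_panel(fr)
  expect_equal(f4(fp, "A", "A2", "C", "D", blocks = 10)$estimate, 0)
  ab <- f4(fp, "A", "B", "C", "D", blocks = 10)
  ba <- f4(fp, "B", "A", "C", "D", blocks = 10)
  expect_equal(ab$estimate, -ba$estimate, tolerance = 1e-12)
  expect_equal(ab$se, ba$se, tolerance = 1e-12)
  dc <- f4(fp, "A", "B", "D", "C", blocks = 10)
  expect_equal(ab$estimate + dc$estimate, 0, tolerance = 1e-12)
  cd <- f4(fp, "C", "D", "A", "B", blocks = 10)
  expect_equal(ab$estimate, cd$estimate, tolerance = 1e-12)
})

test_that("statistics are invariant to site order and block relabeling", {
  set.seed(8)
  fr <- matrix(runif(300), 100, 3,
               dimnames = list(NULL, c("A", "B", "C")))
  fp <- freq_panel(fr)
  ids <- rep(1:10, each = 10)
  a <- f3(fp, "A", "B", "C", blocks = ids, correct = FALSE)
  # relabel blocks
  b <- f3(fp, "A", "B", "C", blocks = 11 - ids, correct = FALSE)
  expect_equal(a$estimate, b$estimate)
  expect_equal(a$se, b$se, tolerance = 1e-12)
})

test_that("f3 on identical populations is non-negative without correction", {
  set.seed(2)
  p <- runif(200)
  fp <- freq_panel(cbind(A = p, B = p, C = p))
  r <- f3(fp, "A", "B", "C", blocks = 10, correct = FALSE)
  expect_true(r$estimate >= 0)
})

test_that("admixed target yields significantly negative f3", {
  nodes <- tibble::tibble(
    name = c("root", "A", "B", "T"),
    parent = c(NA, "root", "root", NA),
    f = c(0, 0.15, 0.15, 0.02),
    mix = list(NULL, NULL, NULL, c(A = 0.5, B = 0.5)))
  fp <- simulate_freq_panel(nodes, n_sites = 1e5, seed = 31)
  r <- f3(fp, "A", "B", "T", blocks = 50, correct = FALSE)
  expect_lt(r$estimate, 0)
  expect_lt(r$z, -3)
})

test_that("block jackknife closed forms and brute-force agreement", {
  jk <- block_jackknife(c(3, 3, 3), c(10, 20, 30))
  expect_equal(jk$se, 0)
  x <- 0.4; y <- 1.0
  jk2 <- block_jackknife(c(x, y), c(5, 5))
  expect_equal(jk2$se, abs(x - y) / 2, tolerance = 1e-12)
  expect_error(block_jackknife(1, 5), ">= 2")
  # brute-force delete-one on random data, equal weights
  set.seed(3)
  v <- rnorm(20); w <- rep(7, 20)
  jk3 <- block_jackknife(v, w)
  est <- mean(v)
  loo <- vapply(1:20, function(i) mean(v[-i]), numeric(1))
  se_brute <- sqrt((19 / 20) * sum((loo - mean(loo))^2))
  expect_equal(jk3$estimate, est, tolerance = 1e-12)
  expect_equal(jk3$se, se_brute, tolerance = 1e-9)
})

test_that("Hudson FST limits and drift recovery", {
  n <- 500
  p <- runif(n, 0.2, 0.8)
  # population frequencies known exactly (infinite sample): no correction
  fp_same <- freq_panel(cbind(A = p, B = p))
  expect_equal(hudson_fst(fp_same, "A", "B", blocks = 10)$estimate, 0,
               tolerance = 1e-12)
  fp_fixed <- freq_panel(cbind(A = rep(1, n), B = rep(0, n)))
  expect_equal(hudson_fst(fp_fixed, "A", "B", blocks = 10)$estimate, 1)
  # two populations drifted from a common ancestor with known F
  Ftrue <- 0.05
  nodes <- tibble::tibble(name = c("root", "A", "B"),
                          parent = c(NA, "root", "root"),
                          f = c(0, Ftrue, Ftrue))
  fp <- simulate_freq_panel(nodes, n_sites = 5e4, seed = 77)
  r <- hudson_fst(fp, "A", "B", blocks = 50)
  # with exact frequencies the estimator converges to the per-branch F
  # (numerator E = 2F p(1-p), denominator E = 2 p(1-p))
  expect_lt(abs(r$estimate - Ftrue), 2 * r$se + 0.003)
})

test_that("qpWave rank tests behave under null and constructed mixtures", {
  # left populations with identical history relative to right: rank 0
  nodes <- tibble::tibble(
    name = c("root", "L0", "L1", "R0", "R1", "R2"),
    parent = c(NA, "anc", "anc", "root", "root", "root"),
    f = c(0, 0.02, 0.02, 0.2, 0.25, 0.3))
  nodes <- dplyr::bind_rows(
    tibble::tibble(name = "anc", parent = "root", f = 0.1), nodes)
  fp <- simulate_freq_panel(nodes, n_sites = 1e5, seed = 41)
  rw <- qpwave_rank(fp, c("L0", "L1"), c("R0", "R1", "R2"), blocks = 50)
  expect_gt(rw$table$p_value[rw$table$rank == 0], 0.05)
  expect_error(qpwave_rank(fp, c("L0", "L1", "R0"), c("R1", "R2")),
               "at least as many")
})

test_that("qpAdm on an exact frequency mixture returns the mixing vector", {
  set.seed(9)
  n <- 2000
  S1 <- runif(n); S2 <- runif(n)
  R <- matrix(runif(3 * n), n, 3,
              dimnames = list(NULL, c("R1", "R2", "R3")))
  w_true <- c(0.7, 0.3)
  Tgt <- w_true[1] * S1 + w_true[2] * S2
  fp <- freq_panel(cbind(T = Tgt, S1 = S1, S2 = S2, R))
  res <- qpadm(fp, "T", c("S1", "S2"), c("R1", "R2", "R3"), blocks = 10)
  expect_equal(res$weights$weight, w_true, tolerance = 1e-6)
  expect_equal(sum(res$weights$weight), 1, tolerance = 1e-10)
  expect_true(res$feasible)
})

test_that("qpAdm recovers simulated mixtures within 2 SE", {
  fx <- make_qpadm_fixture(n_sites = 4e4,
                           alphas = c(Lajia_LN = 0.7, Taiwan_Hanben = 0.3),
                           seed = 5)
  res <- qpadm(fx$fp, fx$target, fx$sources, fx$outgroups, blocks = 40)
  expect_lt(abs(res$weights$weight[1] - 0.7), 2 * res$weights$se[1] + 0.02)
  expect_equal(sum(res$weights$weight), 1, tolerance = 1e-8)
  # target identical to source 1 (alpha boundary)
  fx1 <- make_qpadm_fixture(n_sites = 4e4,
                            alphas = c(Lajia_LN = 1, Taiwan_Hanben = 0),
                            seed = 6)
  res1 <- qpadm(fx1$fp, fx1$target, fx1$sources, fx1$outgroups, blocks = 40)
  expect_lt(abs(res1$weights$weight[1] - 1), 2 * res1$weights$se[1] + 0.02)
})

test_that("collinear-ish inputs raise errors rather than nonsense", {
  set.seed(10)
  n <- 500
  S1 <- runif(n)
  R <- matrix(runif(3 * n), n, 3, dimnames = list(NULL, c("R1", "R2", "R3")))
  fp <- freq_panel(cbind(T = S1, S1 = S1, R))
  expect_error(qpadm(fp, "T", c("S1"), c("R1", "R2", "R3")), "at least 2")
  expect_error(qpadm(fp, "T", c("S1", "R1"), c("R1", "R2", "R3")), "overlap")
})
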