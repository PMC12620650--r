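make_obs <- function(panel, counts, mono = 0, min_count = -1) {
  s <- joint_sfs(panel, counts, monomorphic = mono)
  mask_low_count_entries(s, min_count)
}

make_exp <- function(panel, probs, mono = NULL, n_sims = 1e6) {
  if (is.null(mono)) mono <- 1 - sum(probs)
  e <- joint_sfs(panel, probs, monomorphic = mono, kind = "expected")
  attr(e, "n_sims") <- n_sims
  e
}

test_that("composite log-likelihood matches hand arithmetic", {
  panel <- population_panel("A", 2)
  obs <- make_obs(panel, c(0, 3, 1))
  ex <- make_exp(panel, c(0, 0.75, 0.25), mono = 0)
  ll <- composite_log_likelihood(obs, ex, include_monomorphic = FALSE)
  expect_equal(ll, 3 * log10(0.75) + 1 * log10(0.25), tolerance = 1e-10)
  expect_equal(ll, -0.976877, tolerance = 1e-5)
})

test_that("likelihood is maximal when expectation matches the data", {
  set.seed(1)
  panel <- population_panel("A", 6)
  p_true <- c(0, 0.4, 0.25, 0.15, 0.1, 0.06, 0.04)
  m <- c(0, round(p_true[-1] * 1000))
  obs <- make_obs(panel, m)
  ll_true <- composite_log_likelihood(obs, make_exp(panel, p_true, mono = 0),
                                      include_monomorphic = FALSE)
  worse <- 0
  for (i in 1:100) {
    q <- p_true[-1] * exp(stats::rnorm(6, 0, 0.3))
    q <- q / sum(q)
    ll_q <- composite_log_likelihood(obs, make_exp(panel, c(0, q), mono = 0),
                                     include_monomorphic = FALSE)
    if (ll_q <= ll_true) worse <- worse + 1
  }
  expect_equal(worse, 100)
})

test_that("masked cells pool into a residual and empty support warns", {
  panel <- population_panel("A", 4)
  obs <- make_obs(panel, c(0, 10, 2, 3, 0), min_count = 5)
  ex <- make_exp(panel, c(0, 0.5, 0.2, 0.2, 0.1), mono = 0)
  ll <- composite_log_likelihood(obs, ex, include_monomorphic = FALSE)
  # cell with count 10 retained; all other (masked) cells pool into one
  # residual whose probability is their total mass, 0.2 + 0.2 + 0.1
  expect_equal(ll, 10 * log10(0.5) + 5 * log10(0.5), tolerance = 1e-10)
  obs_all_masked <- make_obs(panel, c(0, 1, 2, 3, 0), min_count = 5)
  expect_warning(
    ll0 <- composite_log_likelihood(obs_all_masked, ex,
                                    include_monomorphic = FALSE),
    "masked")
  expect_equal(ll0, 0)
})

test_that("shape and panel mismatches error", {
  obs <- make_obs(population_panel("A", 4), c(0, 8, 9, 7, 0))
  ex <- make_exp(population_panel("A", 2), c(0, 0.6, 0.4), mono = 0)
  expect_error(composite_log_likelihood(obs, ex), "shape")
})

test_that("ECM recovers a single split time on synthetic data", {
  m <- two_pop_model(t = 200, ne = 1e4)
  mm <- m
  mm$splits$time <- "T_split"
  # ~1e5 SNPs: enough data that the ML itself sits within a few percent
  # of the generating value, so the check measures the optimizer
  g <- simulate_genotypes(sim_spec(m, sample_sizes = c(A = 4, B = 4),
                                   length = 6e7, seed = 5))
  obs <- build_joint_sfs(g, population_panel(c("A", "B"), c(8, 8)))
  space <- tibble::tibble(name = "T_split", min = 20, max = 1000,
                          scale = "log")
  cfg <- fit_config(n_sims = 1e4, n_ecm_cycles = 20,
                    n_cycles_with_monomorphic = 4, n_replicates = 10,
                    seed = 2)
  fit <- ecm_optimize(obs, mm, space, cfg)
  expect_equal(fit$theta_hat[["T_split"]], 200, tolerance = 0.15)
  expect_equal(fit$ml_replicate,
               fit$replicates$replicate[
                 which.max(fit$replicates$loglik_select)])
  # determinism: identical seeds give identical trajectories
  cfg_small <- fit_config(n_sims = 2000, n_ecm_cycles = 4,
                          n_cycles_with_monomorphic = 2, n_replicates = 2,
                          seed = 5)
  fa <- ecm_optimize(obs, mm, space, cfg_small)
  fb <- ecm_optimize(obs, mm, space, cfg_small)
  expect_identical(fa$replicates, fb$replicates)
})

test_that("parameters at the range boundary raise the boundary flag", {
  m <- two_pop_model(t = 100, ne = 1e4)
  mm <- m; mm$splits$time <- "T_split"
  g <- simulate_genotypes(sim_spec(m, sample_sizes = c(A = 2, B = 2),
                                   length = 2e7, seed = 6))
  obs <- build_joint_sfs(g, population_panel(c("A", "B"), c(4, 4)))
  # range entirely above the truth pins the optimum to the lower bound
  space <- tibble::tibble(name = "T_split", min = 500, max = 900,
                          scale = "log")
  cfg <- fit_config(n_sims = 1e4, n_ecm_cycles = 4,
                    n_cycles_with_monomorphic = 1, n_replicates = 2, seed = 3)
  fit <- ecm_optimize(obs, mm, space, cfg)
  expect_true(any(fit$replicates$boundary))
})

test_that("likelihood re-estimation has the configured size and spread", {
  m <- two_pop_model(t = 300)
  mm <- m; mm$splits$time <- "T_split"
  g <- simulate_genotypes(sim_spec(m, sample_sizes = c(A = 2, B = 2),
                                   length = 5e6, seed = 8))
  obs <- build_joint_sfs(g, population_panel(c("A", "B"), c(4, 4)))
  space <- tibble::tibble(name = "T_split", min = 50, max = 900, scale = "log")
  cfg <- fit_config(n_sims = 2000, n_ecm_cycles = 4,
                    n_cycles_with_monomorphic = 2, n_replicates = 2,
                    n_reestimate = 25, seed = 4)
  fit <- ecm_optimize(obs, mm, space, cfg)
  fit <- reestimate_likelihood(fit)
  expect_length(fit$reestimated, 25)
  # Monte-Carlo spread shrinks as simulations per draw grow
  spread <- vapply(c(500, 2000, 8000, 32000), function(ns) {
    cfg2 <- cfg; cfg2$n_sims_reestimate <- ns; cfg2$n_reestimate <- 12
    stats::var(reestimate_likelihood(fit, cfg = cfg2)$reestimated)
  }, numeric(1))
  expect_true(spread[4] < spread[1])
})

test_that("model selection applies the strict exceeds-threshold rule", {
  fake_fit <- function(initial, reest) {
    structure(list(
      replicates = tibble::tibble(replicate = 1, loglik = initial,
                                  loglik_select = initial,
                                  boundary = FALSE, failed = FALSE),
      ml_replicate = 1, reestimated = reest), class = "sfs_fit")
  }
  a <- fake_fit(-100, rep(-100, 10))
  b <- fake_fit(-160, rep(-150, 10))   # mean diff exactly 50
  sel <- select_model(list(A = a, B = b), threshold = 50)
  expect_equal(sel$best, "A")
  expect_false(sel$decisive)           # strict '>': 50.0 is not enough
  b2 <- fake_fit(-160, rep(-151, 10))  # mean diff 51
  sel2 <- select_model(list(A = a, B = b2), threshold = 50)
  expect_true(sel2$decisive)
  # condition (i) fails: higher mean but lower initial likelihood
  c1 <- fake_fit(-90, rep(-151, 10))
  sel3 <- select_model(list(A = a, C = c1), threshold = 50)
  expect_false(sel3$decisive)
  expect_error(select_model(list(A = a)), "at least 2")
})

test_that("rescaling multiplies times/sizes and divides rates", {
  scn <- scenario_library("base_common_origin")
  fit <- structure(list(
    theta_hat = c(T_han = 100, T_tib = 50, T_deep = 200),
    replicates = tibble::tibble(replicate = 1, T_han = 100, T_tib = 50,
                                T_deep = 200, loglik = -1),
    model = scn$model, rescaling_factor = 1), class = "sfs_fit")
  r1 <- rescale_parameters(fit, 1000, 1000)
  expect_equal(r1$theta_hat, fit$theta_hat)
  r2 <- rescale_parameters(fit, 2000, 1000)
  expect_equal(unname(r2$theta_hat), unname(fit$theta_hat) * 2)
  expect_equal(r2$rescaling_factor, 2)
  expect_error(rescale_parameters(fit, 10, 0), "> 0")
})

test_that("nearest-rank percentiles match the order-statistic oracle", {
  x <- stats::rnorm(100)
  s <- sort(x)
  expect_equal(percentile_nearest_rank(x, 0.025), s[3])
  expect_equal(percentile_nearest_rank(x, 0.975), s[98])
  expect_equal(percentile_nearest_rank(x, 1), s[100])
  y <- c(5, 1, 9)
  expect_equal(percentile_nearest_rank(y, 0.5), 5)
})

test_that("degenerate one-block bootstrap gives a zero-width CI", {
  m <- two_pop_model(t = 300)
  mm <- m; mm$splits$time <- "T_split"
  g <- simulate_genotypes(sim_spec(m, sample_sizes = c(A = 2, B = 2),
                                   length = 9e5, seed = 14))
  panel <- population_panel(c("A", "B"), c(4, 4))
  blocks <- make_blocks(g, span_bp = 1e6)
  expect_equal(nrow(blocks$blocks), 1)
  boot <- bootstrap_sfs(g, panel, blocks, n_boot = 4, seed = 2)
  space <- tibble::tibble(name = "T_split", min = 50, max = 900, scale = "log")
  cfg <- fit_config(n_sims = 1000, n_ecm_cycles = 2,
                    n_cycles_with_monomorphic = 1, n_replicates = 1, seed = 9)
  ci <- bootstrap_ci(boot, mm, space, cfg, runs_per_boot = 1)
  expect_equal(ci$ci$lower, ci$ci$upper)
})

test_that("rescaled parameters reproduce the observed SNP yield", {
  mk <- function(t) demog_model(
    populations = tibble::tibble(name = c("A", "B"), size = 1e4),
    splits = tibble::tibble(time = t, derived = "B", ancestral = "A",
                            size = 1e4))
  mm <- mk(200); mm$splits$time <- "T_split"
  mm$populations$size <- c("N_a", "N_a")
  mm$splits$size <- "N_a"
  expected_snps <- function(th, seed = 3) {
    e <- expected_sfs(sim_spec(mm, th, sample_sizes = c(A = 2, B = 2),
                               n_reps = 2e4, seed = seed))
    sum(e$counts) * 1e7  # per-site polymorphic probability x genome length
  }
  theta <- c(T_split = 200, N_a = 1e4)
  base <- expected_snps(theta)
  obs_snps <- 1.5 * base  # pretend the data carried 50% more SNPs
  fit <- structure(list(
    theta_hat = theta,
    replicates = tibble::tibble(replicate = 1, T_split = 200, N_a = 1e4,
                                loglik = -1),
    model = mm, rescaling_factor = 1), class = "sfs_fit")
  fit2 <- rescale_parameters(fit, obs_snps, base)
  redo <- expected_snps(fit2$theta_hat)
  expect_lt(abs(redo - obs_snps) / obs_snps, 0.1)
})
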