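#' Fitting protocol configuration
#'
#' Bundles the composite-likelihood estimation settings: coalescent
#' simulations per likelihood evaluation, expectation-conditional-
#' maximization (ECM) cycles, how many initial cycles include the
#' monomorphic cell, replicate runs from random starts, the low-count mask
#' threshold and the master seed.  Production-scale settings mirror common
#' practice for SFS composite-likelihood fitting (6e5 simulations, 65
#' cycles with the first 25 monomorphic-aware, 100 replicates); reduced
#' settings are appropriate for desk-scale recovery experiments.
#'
#' @param n_sims coalescent genealogies per likelihood evaluation.
#' @param n_ecm_cycles ECM cycles per replicate run.
#' @param n_cycles_with_monomorphic leading cycles in which the likelihood
#'   includes the monomorphic cell (must not exceed `n_ecm_cycles`).
#' @param n_replicates independent replicate runs from random starts.
#' @param min_count SFS entries with counts `<= min_count` are pooled into
#'   a residual cell during estimation.
#' @param n_reestimate number of expected-SFS draws for likelihood
#'   re-estimation.
#' @param n_sims_reestimate simulations per re-estimation draw.
#' @param n_sims_select simulations for the final common-seed likelihood
#'   used to designate the maximum-likelihood replicate (the analogue of
#'   re-computing each run's likelihood with many more simulations than
#'   the optimization used; default 17x `n_sims`, mirroring the 1e7 / 6e5
#'   production ratio).
#' @param seed master seed; every replicate and cycle derives its stream
#'   deterministically from it.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(n_sims = 6e5, n_ecm_cycles = 65,
                       n_cycles_with_monomorphic = 25, n_replicates = 100,
                       min_count = 5, n_reestimate = 100,
                       n_sims_reestimate = n_sims,
                       n_sims_select = round(17 * n_sims), seed = 1) {
  if (n_cycles_with_monomorphic > n_ecm_cycles)
    abort("n_cycles_with_monomorphic must be <= n_ecm_cycles")
  if (any(c(n_sims, n_ecm_cycles, n_replicates, n_reestimate,
            n_sims_reestimate) < 1))
    abort("all counts must be >= 1")
  structure(list(n_sims = n_sims, n_ecm_cycles = n_ecm_cycles,
                 n_cycles_with_monomorphic = n_cycles_with_monomorphic,
                 n_replicates = n_replicates, min_count = min_count,
                 n_reestimate = n_reestimate,
                 n_sims_reestimate = n_sims_reestimate,
                 n_sims_select = n_sims_select, seed = seed),
            class = "fit_config")
}

# deterministic 31-bit sub-seed derivation
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed %% 2147483647)
  for (i in ix) s <- (s * 48271 + i * 8191 + 1) %% 2147483647
  s
}

#' Composite log10-likelihood of an observed joint SFS
#'
#' Multinomial composite likelihood over SFS cells: the sum over retained
#' cells of count times log10 of the expected cell probability.  Cells
#' masked as low-count are pooled into a single residual cell.  Expected
#' probabilities are floored at a small pseudo-probability so that cells
#' unobserved in the Monte-Carlo expectation cannot zero out the
#' likelihood; when the monomorphic cell is excluded, expected
#' probabilities are renormalized over the polymorphic support.
#'
#' @param obs observed `joint_sfs` (integer counts; `mask` honoured if set).
#' @param exp expected `joint_sfs` (probabilities from [expected_sfs()]).
#' @param include_monomorphic include the monomorphic cell's contribution.
#' @param pseudo_floor lower floor for expected probabilities; defaults to
#'   `1 / (10 * n_sims)` where `n_sims` is taken from `exp`, or 1e-8.
#' @param pool_residual pool masked cells into one residual cell (the
#'   default); `FALSE` drops them instead, conditioning the multinomial on
#'   the retained support.
#' @return log10 composite likelihood (scalar).
#' @export
composite_log_likelihood <- function(obs, exp, include_monomorphic = TRUE,
                                     pseudo_floor = NULL,
                                     pool_residual = TRUE) {
  if (!identical(dim(obs$counts), dim(exp$counts)))
    abort("observed and expected SFS have different shapes")
  if (!identical(obs$panel$pop, exp$panel$pop))
    abort("observed and expected SFS have different panels")
  if (is.null(pseudo_floor)) {
    ns <- attr(exp, "n_sims")
    pseudo_floor <- if (is.null(ns)) 1e-8 else 1 / (10 * ns)
  }
  m <- as.vector(obs$counts)
  p <- as.vector(exp$counts)
  mask <- if (is.null(obs$mask)) c(TRUE, rep(FALSE, length(m) - 1L))
          else as.vector(obs$mask)
  mask[1] <- TRUE
  p_mono <- exp$monomorphic
  tot_poly <- sum(p)
  if (tot_poly <= 0) {
    warn("expected SFS has no polymorphic mass; likelihood set to 0")
    return(0)
  }
  if (!include_monomorphic) p <- p / tot_poly
  # the pseudo-probability floor lives on the polymorphic-conditional scale
  # (a resolution limit of the Monte-Carlo expectation), so rescale it when
  # cells are expressed as absolute per-site probabilities
  floor_eff <- if (include_monomorphic) pseudo_floor * tot_poly else pseudo_floor
  keep <- !mask
  if (sum(m[keep]) == 0 &&
      (!include_monomorphic || obs$monomorphic == 0)) {
    warn("all observed cells masked; likelihood is 0 by convention")
    return(0)
  }
  if (!pool_residual) {
    # condition on the retained support: renormalize and drop the rest
    p <- p / max(sum(p[keep]), floor_eff)
    ll <- sum(m[keep] * log10(pmax(p[keep], floor_eff)))
    if (include_monomorphic && obs$monomorphic > 0)
      ll <- ll + obs$monomorphic * log10(max(p_mono, floor_eff))
    return(ll)
  }
  ll <- sum(m[keep] * log10(pmax(p[keep], floor_eff)))
  m_res <- sum(m[mask])
  if (m_res > 0) {
    p_res <- sum(p[mask])
    ll <- ll + m_res * log10(max(p_res, floor_eff))
  }
  if (include_monomorphic && obs$monomorphic > 0)
    ll <- ll + obs$monomorphic * log10(max(p_mono, floor_eff))
  ll
}


# precompute the compact cell summary of a masked observed SFS used by the
# fast likelihood path: retained-cell indices (0-based), their counts, the
# pooled residual count and the monomorphic count
prep_cll <- function(obs) {
  m <- as.vector(obs$counts)
  mask <- if (is.null(obs$mask)) c(TRUE, rep(FALSE, length(m) - 1L))
          else as.vector(obs$mask)
  mask[1] <- TRUE
  keep <- which(!mask)
  list(idx0 = keep - 1L, m_ret = m[keep], m_res = sum(m[mask]),
       n_mono = obs$monomorphic)
}

# composite log10-likelihood via the compact simulation path; numerically
# identical to composite_log_likelihood() on the full array
fast_cll <- function(model, params, dip, prep, n_sims, seed, include_mono) {
  spec <- sim_spec(model, params, sample_sizes = dip, n_reps = n_sims,
                   seed = seed)
  sf <- spec_flatten(spec)
  res <- sim_expected_cells_cpp(sf$fl$n_pops, sf$fl$samp, sf$fl$init,
                                sf$fl$events, as.integer(n_sims), seed,
                                prep$idx0)
  mu <- sf$bound$mu
  p <- res$cell_len * mu
  tot <- res$total_len * mu
  if (tot <= 0) return(0)
  pf <- 1 / (10 * n_sims)
  if (sum(prep$m_ret) == 0 && (!include_mono || prep$n_mono == 0)) return(0)
  if (include_mono) {
    fl <- pf * tot
    ll <- sum(prep$m_ret * log10(pmax(p, fl)))
    if (prep$m_res > 0)
      ll <- ll + prep$m_res * log10(max(tot - sum(p), fl))
    if (prep$n_mono > 0)
      ll <- ll + prep$n_mono * log10(max(1 - tot, fl))
  } else {
    q <- p / tot
    ll <- sum(prep$m_ret * log10(pmax(q, pf)))
    if (prep$m_res > 0)
      ll <- ll + prep$m_res * log10(max(1 - sum(q), pf))
  }
  ll
}

# clip the 1-D search interval of parameter `pname` to the order
# constraints, given current values of the other parameters
constrained_interval <- function(pname, space, constraints, theta) {
  row <- space[space$name == pname, ]
  lo <- row$min; hi <- row$max
  if (!is.null(constraints) && nrow(constraints)) {
    for (i in seq_len(nrow(constraints))) {
      if (constraints$lower[i] == pname && constraints$upper[i] %in% names(theta))
        hi <- min(hi, theta[[constraints$upper[i]]])
      if (constraints$upper[i] == pname && constraints$lower[i] %in% names(theta))
        lo <- max(lo, theta[[constraints$lower[i]]])
    }
  }
  c(lo, min(hi, row$max))
}

# draw a random start satisfying the constraints (rejection, then sort fix)
random_start <- function(space, constraints, rng) {
  draw <- function() {
    v <- numeric(nrow(space))
    u <- rng(nrow(space))
    for (i in seq_len(nrow(space))) {
      if (space$scale[i] == "log") {
        v[i] <- 10^(log10(space$min[i]) +
                    u[i] * (log10(space$max[i]) - log10(space$min[i])))
      } else {
        v[i] <- space$min[i] + u[i] * (space$max[i] - space$min[i])
      }
    }
    setNames(v, space$name)
  }
  ok <- function(th) {
    if (is.null(constraints) || !nrow(constraints)) return(TRUE)
    all(th[constraints$lower] < th[constraints$upper])
  }
  for (i in 1:200) {
    th <- draw()
    if (ok(th)) return(th)
  }
  # fall back: sort the drawn values into a feasible order along chains
  th <- draw()
  if (!is.null(constraints) && nrow(constraints))
    for (i in seq_len(nrow(constraints))) {
      l <- constraints$lower[i]; u <- constraints$upper[i]
      if (th[[l]] >= th[[u]]) {
        m <- sqrt(th[[l]] * th[[u]])
        th[[l]] <- m * 0.9; th[[u]] <- m * 1.1
      }
    }
  th
}

#' Composite-likelihood parameter estimation by ECM
#'
#' Runs replicate expectation-conditional-maximization searches: each
#' replicate starts from a random point of the parameter space and cycles
#' through one-dimensional maximizations of the composite log10-likelihood,
#' one free parameter at a time (Brent search on the parameter's scale,
#' interval clipped to any order constraints).  Within a cycle all
#' likelihood evaluations share one simulation seed (common random
#' numbers), which keeps the Monte-Carlo likelihood surface smooth in the
#' varied parameter.  The monomorphic cell participates for the first
#' `n_cycles_with_monomorphic` cycles and is dropped afterwards.
#'
#' @param obs observed `joint_sfs`; masked with `cfg$min_count` if not
#'   already masked.
#' @param model `demog_model` with free parameters.
#' @param space parameter-space tibble (`name`, `min`, `max`, `scale`).
#' @param cfg a [fit_config()].
#' @param constraints optional tibble (`lower`, `upper`) of order
#'   constraints between parameters.
#' @param fixed named values for free parameters held fixed (not searched).
#' @return an `sfs_fit` object: per-replicate estimates and log10
#'   composite likelihoods, the maximum-likelihood replicate, and the
#'   ingredients needed for re-estimation and rescaling.
#' @export
ecm_optimize <- function(obs, model, space, cfg, constraints = NULL,
                         fixed = NULL) {
  if (is.null(obs$mask)) obs <- mask_low_count_entries(obs, cfg$min_count)
  space <- space[!space$name %in% names(fixed), , drop = FALSE]
  missing_par <- setdiff(free_params(model),
                         c(space$name, names(fixed)))
  if (length(missing_par))
    abort(paste("free parameters without search range or fixed value:",
                paste(missing_par, collapse = ", ")))
  dip <- setNames(obs$panel$haploids %/% 2L, obs$panel$pop)
  prep <- prep_cll(obs)
  eval_cll <- function(theta, seed, include_mono) {
    fast_cll(model, c(as.list(theta), as.list(fixed)), dip, prep,
             cfg$n_sims, seed, include_mono)
  }
  reps <- vector("list", cfg$n_replicates)
  # fixed tracking seed: cycle-end positions are compared under one
  # simulation stream, and each replicate keeps its best visited point
  # (the ECM trajectory is stochastic; its last position is not its best)
  track_seed <- derive_seed(cfg$seed, 29)
  for (r in seq_len(cfg$n_replicates)) {
    rng <- make_rng(derive_seed(cfg$seed, 11, r))
    theta <- random_start(space, constraints, rng)
    ll <- NA_real_
    failed <- FALSE
    best_theta <- theta
    best_tll <- -Inf
    for (cyc in seq_len(cfg$n_ecm_cycles)) {
      cyc_seed <- derive_seed(cfg$seed, 13, r, cyc)
      inc_mono <- cyc <= cfg$n_cycles_with_monomorphic
      for (j in seq_len(nrow(space))) {
        pname <- space$name[j]
        iv <- constrained_interval(pname, space, constraints, theta)
        if (!(iv[1] < iv[2])) next
        obj <- function(v) {
          th <- theta; th[[pname]] <- v
          -eval_cll(th, cyc_seed, inc_mono)
        }
        opt <- if (space$scale[j] == "log") {
          o <- optimize(function(lv) obj(10^lv), lower = log10(iv[1]),
                        upper = log10(iv[2]), tol = 0.012)
          list(minimum = 10^o$minimum, objective = o$objective)
        } else {
          optimize(obj, lower = iv[1], upper = iv[2],
                   tol = 0.012 * (iv[2] - iv[1]))
        }
        theta[[pname]] <- opt$minimum
        ll <- -opt$objective
      }
      if (!is.finite(ll)) { failed <- TRUE; break }
      tll <- eval_cll(theta, track_seed, include_mono = FALSE)
      if (tll > best_tll) { best_tll <- tll; best_theta <- theta }
    }
    theta <- best_theta
    if (is.finite(best_tll)) ll <- best_tll
    # Brent stops ~1% of the interval short of an endpoint, so flag
    # anything in the outer 5%
    boundary <- any(theta <= space$min * 1.05 | theta >= space$max * 0.95)
    reps[[r]] <- bind_cols(tibble(replicate = r),
                           as_tibble(as.list(theta)),
                           tibble(loglik = ll, boundary = boundary,
                                  failed = failed))
  }
  replicates <- bind_rows(reps)
  usable <- replicates[!replicates$failed & is.finite(replicates$loglik), ]
  if (nrow(usable) == 0) abort("all replicates failed")
  # designate the ML replicate by a common-seed likelihood computed with
  # many more simulations than the cycle-level optimization used
  sel_seed <- derive_seed(cfg$seed, 31)
  nss <- cfg$n_sims_select %||% round(17 * cfg$n_sims)
  replicates$loglik_select <- NA_real_
  for (r in usable$replicate) {
    th <- unlist(replicates[replicates$replicate == r, space$name])
    replicates$loglik_select[replicates$replicate == r] <-
      fast_cll(model, c(as.list(th), as.list(fixed)), dip, prep, nss,
               sel_seed, include_mono = TRUE)
  }
  ml <- replicates$replicate[which.max(replicates$loglik_select)]
  theta_hat <- unlist(replicates[replicates$replicate == ml, space$name])
  structure(list(replicates = replicates, ml_replicate = ml,
                 theta_hat = theta_hat, model = model, space = space,
                 constraints = constraints, fixed = fixed, cfg = cfg,
                 panel = obs$panel, obs = obs,
                 reestimated = NULL, rescaling_factor = 1),
            class = "sfs_fit")
}

#' @export
print.sfs_fit <- function(x, ...) {
  cat("<sfs_fit> ", nrow(x$replicates), " replicates; ML replicate ",
      x$ml_replicate, "\n  theta_hat: ", sep = "")
  cat(paste0(names(x$theta_hat), "=", signif(x$theta_hat, 4),
             collapse = ", "), "\n")
  if (!is.null(x$reestimated))
    cat("  re-estimated log10 L: mean ", signif(mean(x$reestimated), 6),
        " (n=", length(x$reestimated), ")\n", sep = "")
  invisible(x)
}

#' Re-estimate the likelihood of the best run
#'
#' Draws `cfg$n_reestimate` independent Monte-Carlo expected spectra at the
#' maximum-likelihood parameter vector and computes the observed SFS's
#' composite log10-likelihood under each, characterizing the Monte-Carlo
#' spread of the likelihood at the optimum (used by [select_model()]).
#'
#' @param fit an `sfs_fit`.
#' @param obs observed `joint_sfs` (defaults to the SFS stored in the fit).
#' @param cfg a [fit_config()]; defaults to the fit's config.
#' @return the `sfs_fit` with `$reestimated` filled (vector of log10
#'   likelihoods, length `cfg$n_reestimate`).
#' @export
reestimate_likelihood <- function(fit, obs = NULL, cfg = NULL) {
  if (is.null(obs)) obs <- fit$obs
  if (is.null(cfg)) cfg <- fit$cfg
  dip <- setNames(obs$panel$haploids %/% 2L, obs$panel$pop)
  if (is.null(obs$mask)) obs <- mask_low_count_entries(obs, cfg$min_count)
  prep <- prep_cll(obs)
  vals <- vapply(seq_len(cfg$n_reestimate), function(i) {
    fast_cll(fit$model, c(as.list(fit$theta_hat), as.list(fit$fixed)), dip,
             prep, cfg$n_sims_reestimate, derive_seed(cfg$seed, 17, i),
             include_mono = TRUE)
  }, numeric(1))
  fit$reestimated <- vals
  fit
}

#' Decisive model selection on re-estimated likelihoods
#'
#' A model is selected as decisive best fit only if (i) its initial
#' expected log10 composite likelihood (the ML replicate's terminal value)
#' is the highest among the candidates, and (ii) the mean re-estimated
#' log10-likelihood difference to every alternative strictly exceeds the
#' threshold (default 50 log10 units).  Otherwise the result reports "no
#' decisive model" together with the failing comparisons.
#'
#' @param fits named list of `sfs_fit` objects with `$reestimated` filled.
#' @param threshold log10-likelihood difference that must be exceeded.
#' @return a `model_selection` object: tibble of comparisons, the candidate
#'   best model, and a `decisive` flag.
#' @export
select_model <- function(fits, threshold = 50) {
  if (length(fits) < 2) abort("model selection needs at least 2 fitted models")
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    abort("fits must be a named list")
  for (nm in names(fits))
    if (is.null(fits[[nm]]$reestimated))
      abort(paste0("model '", nm, "' lacks re-estimated likelihoods"))
  initial <- vapply(fits, function(f)
    f$replicates$loglik[f$replicates$replicate == f$ml_replicate],
    numeric(1))
  means <- vapply(fits, function(f) mean(f$reestimated), numeric(1))
  best <- names(fits)[which.max(initial)]
  others <- setdiff(names(fits), best)
  comp <- tibble(model = others,
                 mean_diff = means[best] - means[others],
                 exceeds = (means[best] - means[others]) > threshold)
  decisive <- all(comp$exceeds) &&
    all(initial[best] >= initial[others])
  structure(list(best = best, decisive = decisive, threshold = threshold,
                 initial = initial, mean_loglik = means, comparisons = comp),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection> candidate best:", x$best,
      if (x$decisive) "(decisive)" else "(NOT decisive)", "\n")
  print(x$comparisons)
  invisible(x)
}

# which slot kind a free parameter binds to: time, size or rate
param_kind <- function(model, pname) {
  has <- function(x) any(!is.na(x) & grepl(paste0("^", pname, "( *\\+.*)?$"),
                                           as.character(x)))
  if (has(model$splits$time) || has(model$size_changes$t_start) ||
      has(model$size_changes$t_end) || has(model$migrations$t_start) ||
      has(model$migrations$t_end) || has(model$pulses$time)) return("time")
  if (has(model$populations$size) || has(model$splits$size) ||
      has(model$size_changes$size)) return("size")
  if (has(model$migrations$rate)) return("rate")
  "other"
}

#' Rescale fitted parameters to match the observed SNP count
#'
#' Corrects for a discrepancy between the number of observed SNPs and the
#' number expected under the fitted model: with the rescaling factor
#' defined as observed over expected SNP count, population sizes and
#' times multiply by the factor and migration rates divide by it (leaving
#' the expected SFS shape unchanged while matching the polymorphic
#' yield).
#'
#' @param fit an `sfs_fit`.
#' @param obs_snp_count number of observed polymorphic sites.
#' @param expected_snp_count expected polymorphic sites under the fitted
#'   model (> 0).
#' @return the `sfs_fit` with rescaled `theta_hat`/replicates and the
#'   factor recorded in `$rescaling_factor`.
#' @export
rescale_parameters <- function(fit, obs_snp_count, expected_snp_count) {
  if (expected_snp_count <= 0) abort("expected_snp_count must be > 0")
  r <- obs_snp_count / expected_snp_count
  if (r <= 0) abort("rescaling factor must be > 0")
  for (pname in names(fit$theta_hat)) {
    k <- param_kind(fit$model, pname)
    f <- switch(k, time = r, size = r, rate = 1 / r, 1)
    fit$theta_hat[[pname]] <- fit$theta_hat[[pname]] * f
    fit$replicates[[pname]] <- fit$replicates[[pname]] * f
  }
  fit$rescaling_factor <- r
  fit
}

#' Nearest-rank percentile
#'
#' The q-th percentile as the ceiling(q n)-th order statistic; with 100
#' sorted bootstrap values the 95% interval is the (3rd, 98th) pair.
#'
#' @param x numeric vector.
#' @param q probability in (0, 1].
#' @return the nearest-rank percentile value.
#' @export
percentile_nearest_rank <- function(x, q) {
  s <- sort(x)
  s[max(1L, ceiling(q * length(s)))]
}

#' Block-bootstrap confidence intervals for fitted parameters
#'
#' Refits the model on block-bootstrap SFS replicates (a reduced number of
#' replicate runs each, keeping the best), and reports per-parameter 95%
#' intervals as nearest-rank 2.5th/97.5th percentiles of the bootstrap ML
#' estimates.
#'
#' @param boot list of bootstrap `joint_sfs` replicates (from
#'   [bootstrap_sfs()]).
#' @param model,space,constraints as in [ecm_optimize()].
#' @param cfg a [fit_config()]; `runs_per_boot` overrides its replicate
#'   count within each bootstrap.
#' @param runs_per_boot replicate runs per bootstrap dataset.
#' @param fixed named fixed parameter values (as in [ecm_optimize()]).
#' @param level confidence level (default 0.95).
#' @return a `boot_ci` object: tibble of per-parameter intervals, the
#'   bootstrap estimates, and the count of failed bootstraps.
#' @export
bootstrap_ci <- function(boot, model, space, cfg, constraints = NULL,
                         runs_per_boot = 20, fixed = NULL, level = 0.95) {
  n_boot <- length(boot)
  if (n_boot < 1) abort("need at least one bootstrap replicate")
  cfg_b <- cfg
  cfg_b$n_replicates <- runs_per_boot
  est <- vector("list", n_boot)
  failed <- 0L
  # one common seed across bootstraps: interval width then reflects
  # resampling variation in the data, not optimizer randomness, and
  # degenerate (single-block) data collapse to a zero-width interval
  cfg_b$seed <- derive_seed(cfg$seed, 23)
  for (b in seq_len(n_boot)) {
    fit_b <- tryCatch(
      ecm_optimize(boot[[b]], model, space, cfg_b,
                   constraints = constraints, fixed = fixed),
      error = function(e) NULL)
    if (is.null(fit_b)) { failed <- failed + 1L; next }
    est[[b]] <- fit_b$theta_hat
  }
  est <- do.call(rbind, est)
  if (is.null(est) || nrow(est) < 0.8 * n_boot)
    abort(paste0(failed, " of ", n_boot,
                 " bootstraps failed; too few survivors for a CI"))
  alpha <- (1 - level) / 2
  ci <- tibble(
    param = colnames(est),
    lower = apply(est, 2, percentile_nearest_rank, q = alpha),
    upper = apply(est, 2, percentile_nearest_rank, q = 1 - alpha))
  structure(list(ci = ci, estimates = as_tibble(est), n_failed = failed,
                 level = level),
            class = "boot_ci")
}

#' @export
print.boot_ci <- function(x, ...) {
  cat("<boot_ci> ", nrow(x$estimates), " bootstraps (",
      x$n_failed, " failed), level ", x$level, "\n", sep = "")
  print(x$ci)
  invisible(x)
}
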