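#' Weighted block jackknife
#'
#' Delete-one-block jackknife estimate and standard error for a statistic
#' that is a ratio/mean over genomic blocks, with block weights (usually
#' usable site counts).  Uses the weighted-jackknife variance form, which
#' reduces to the classic delete-one formulas at equal weights.
#'
#' @param values per-block statistic values (the delete-one estimates are
#'   recomputed internally from `values` and `weights` when `loo = NULL`).
#' @param weights per-block weights (>= 0, at least two positive).
#' @param loo optional vector of delete-one-block estimates; when omitted
#'   they are reconstructed from the weighted block values.
#' @param estimate optional full-data estimate; defaults to the weighted
#'   mean of `values`.
#' @return list with `estimate`, `se`, `n_blocks`.
#' @export
block_jackknife <- function(values, weights, loo = NULL, estimate = NULL) {
  keep <- weights > 0
  values <- values[keep]; weights <- weights[keep]
  B <- length(values)
  if (B < 2) abort("block jackknife needs >= 2 blocks with weight")
  n <- sum(weights)
  if (is.null(estimate)) estimate <- sum(values * weights) / n
  if (is.null(loo)) {
    loo <- (estimate * n - values * weights) / (n - weights)
  } else {
    loo <- loo[keep]
  }
  h <- n / weights
  theta_j <- B * estimate - sum((1 - weights / n) * loo)
  tau <- h * estimate - (h - 1) * loo
  se <- sqrt(mean((tau - theta_j)^2 / (h - 1)))
  list(estimate = estimate, se = se, n_blocks = B)
}

# assign freq-panel sites to blocks; returns integer block id per site
panel_block_ids <- function(fp, blocks) {
  if (inherits(blocks, "block_index")) {
    key <- paste(fp$sites$chrom, (fp$sites$pos - 1) %/% blocks$span_bp)
    return(match(key, unique(key)))
  }
  if (is.numeric(blocks) && length(blocks) == 1) {
    # interpret as a block count: contiguous site blocks of equal size
    nb <- as.integer(blocks)
    return(as.integer(cut(seq_len(nrow(fp$freq)), nb)))
  }
  as.integer(blocks)
}

fstat_result <- function(stat, pops, estimate, se, n_blocks, n_sites) {
  tibble(stat = stat, pops = paste(pops, collapse = ","),
         estimate = estimate, se = se,
         z = ifelse(se > 0, estimate / se, NA_real_),
         n_blocks = n_blocks, n_sites = n_sites)
}

# generic per-site f-statistic (ratio of block averages) -> jackknifed tibble
jackknife_stat <- function(fp, num, blocks, stat, pops, denom = NULL) {
  if (is.null(denom)) denom <- rep(1, length(num))
  ok <- is.finite(num) & is.finite(denom)
  if (!any(ok)) abort("no usable sites (listwise-complete across populations)")
  ids <- panel_block_ids(fp, blocks)[ok]
  num <- num[ok]
  dn <- denom[ok]
  bw <- tapply(dn, ids, sum)
  bs <- tapply(num, ids, sum) / bw
  est <- sum(num) / sum(dn)
  jk <- block_jackknife(as.numeric(bs), as.numeric(bw), estimate = est)
  fstat_result(stat, pops, jk$estimate, jk$se, jk$n_blocks, length(num))
}

#' f3 statistic
#'
#' `f3(A, B; C)` is the mean over sites of `(c - a)(c - b)`: the covariance
#' of the target C's allele-frequency deviations from two reference
#' populations.  Significantly negative values indicate that C is admixed
#' between sources related to A and B; with an outgroup as C ("outgroup
#' f3") larger values indicate more shared drift between A and B.  When
#' sampled allele counts are available, the target's finite-sample
#' heterozygosity bias is subtracted (`correct = TRUE`).
#'
#' @param fp a `freq_panel`.
#' @param a,b source population names.
#' @param c target population name.
#' @param blocks a `block_index`, a per-site block-id vector, or a single
#'   number of contiguous site blocks.
#' @param correct subtract the target heterozygosity correction
#'   `c(1-c)/(n_c - 1)` (needs finite counts in `fp$n_obs`).
#' @return one-row tibble: estimate, block-jackknife SE, Z, block and site
#'   counts.
#' @export
f3 <- function(fp, a, b, c, blocks = 40, correct = TRUE) {
  pa <- fp$freq[, a]; pb <- fp$freq[, b]; pc <- fp$freq[, c]
  num <- (pc - pa) * (pc - pb)
  if (correct) {
    nc <- fp$n_obs[, c]
    corr <- ifelse(is.finite(nc) & nc > 1, pc * (1 - pc) / (nc - 1), 0)
    num <- num - corr
  }
  jackknife_stat(fp, num, blocks, "f3", c(a, b, c))
}

#' f4 statistic
#'
#' `f4(A, B; C, D)` is the mean over sites of `(a - b)(c - d)`, measuring
#' correlated allele-frequency differences between the two pairs (shared
#' drift between the unordered pairs).  Zero under treeness of the quartet;
#' its block-jackknife Z is the standard test for admixture.
#'
#' @inheritParams f3
#' @param a,b,c,d population names.
#' @return one-row tibble as in [f3()].
#' @export
f4 <- function(fp, a, b, c, d, blocks = 40) {
  num <- (fp$freq[, a] - fp$freq[, b]) * (fp$freq[, c] - fp$freq[, d])
  jackknife_stat(fp, num, blocks, "f4", c(a, b, c, d))
}

#' Hudson FST (ratio of averages)
#'
#' Hudson's estimator with finite-sample correction: per-site numerator
#' `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and denominator
#' `p1(1-p2) + p2(1-p1)`, combined as the ratio of genome-wide averages
#' (robust to rare-variant weighting), with a block-jackknife SE.
#'
#' @inheritParams f3
#' @param a,b population names.
#' @return one-row tibble as in [f3()].
#' @export
hudson_fst <- function(fp, a, b, blocks = 40) {
  p1 <- fp$freq[, a]; p2 <- fp$freq[, b]
  n1 <- fp$n_obs[, a]; n2 <- fp$n_obs[, b]
  c1 <- ifelse(is.finite(n1) & n1 > 1, p1 * (1 - p1) / (n1 - 1), 0)
  c2 <- ifelse(is.finite(n2) & n2 > 1, p2 * (1 - p2) / (n2 - 1), 0)
  num <- (p1 - p2)^2 - c1 - c2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- is.finite(num) & is.finite(den) & den > 0
  if (!any(ok)) abort("no usable sites")
  fp2 <- fp
  num[!ok] <- NA
  jackknife_stat(fp2, num, blocks, "fst", c(a, b), denom = ifelse(ok, den, NA))
}

# ---- qpWave / qpAdm -----------------------------------------------------

# f4 matrix X[i, j] = f4(left_i, left_1; right_j, right_1) per block and
# total, with block weights = usable sites
f4_matrix_blocks <- function(fp, left, right, blocks) {
  use <- c(left, right)
  ok <- rowSums(!is.finite(fp$freq[, use, drop = FALSE])) == 0
  if (!any(ok)) abort("no sites complete across left and right populations")
  ids <- panel_block_ids(fp, blocks)[ok]
  fr <- fp$freq[ok, , drop = FALSE]
  nl <- length(left) - 1; nr <- length(right) - 1
  d_l <- fr[, left[-1], drop = FALSE] - fr[, left[1]]
  d_r <- fr[, right[-1], drop = FALSE] - fr[, right[1]]
  ub <- sort(unique(ids))
  B <- length(ub)
  Xb <- array(0, c(B, nl, nr))
  wb <- numeric(B)
  for (bi in seq_len(B)) {
    rows <- ids == ub[bi]
    wb[bi] <- sum(rows)
    Xb[bi, , ] <- crossprod(d_l[rows, , drop = FALSE],
                            d_r[rows, , drop = FALSE])
  }
  Xtot <- apply(Xb, c(2, 3), sum) / sum(wb)
  list(Xb = Xb, wb = wb, X = Xtot, nl = nl, nr = nr, n_sites = sum(wb))
}

# delete-one-block f4 matrices (vectorized over cells)
f4_loo <- function(fb) {
  B <- length(fb$wb)
  tot <- apply(fb$Xb, c(2, 3), sum)
  n <- sum(fb$wb)
  loo <- array(0, dim(fb$Xb))
  for (bi in seq_len(B))
    loo[bi, , ] <- (tot - fb$Xb[bi, , ]) / (n - fb$wb[bi])
  loo
}

# block-jackknife covariance of vec(X)
f4_jack_cov <- function(fb) {
  loo <- f4_loo(fb)
  B <- length(fb$wb)
  n <- sum(fb$wb)
  h <- n / fb$wb
  Xv <- as.vector(fb$X)
  L <- matrix(loo, nrow = B)
  theta_j <- B * Xv - colSums((1 - fb$wb / n) * L)
  tau <- outer(h, Xv) - (h - 1) * L
  dev <- sweep(tau, 2, theta_j)
  V <- crossprod(dev / sqrt(h - 1)) / B
  # guard against numerically singular covariance with a small ridge
  V + diag(1e-12 * max(sum(diag(V)), 1e-30), nrow(V))
}

#' qpWave rank test
#'
#' Tests how many independent ancestry streams relate a set of `left`
#' populations to a set of `right` (outgroup) populations: forms the f4
#' matrix `X[i,j] = f4(left_i, left_1; right_j, right_1)`, estimates its
#' rank by minimizing the quadratic form under the block-jackknife
#' covariance of `vec(X)`, and reports a chi-square tail probability for
#' each rank `0 .. |left|-2` with `(|left|-1-r)(|right|-1-r)` degrees of
#' freedom.  Rank `r` adequate means `left` relates to `right` through
#' `r + 1` ancestry streams.
#'
#' @param fp a `freq_panel`.
#' @param left character vector of >= 2 left populations.
#' @param right character vector of outgroups, `|right| >= |left|`,
#'   disjoint from `left`.
#' @param blocks block specification (see [f3()]).
#' @return a `qpwave_result`: tibble with `rank`, `statistic`, `dof`,
#'   `p_value`.
#' @export
qpwave_rank <- function(fp, left, right, blocks = 40) {
  if (length(left) < 2) abort("need at least 2 left populations")
  if (length(right) < length(left))
    abort("need at least as many right as left populations")
  if (length(intersect(left, right)))
    abort("left and right sets must be disjoint")
  fb <- f4_matrix_blocks(fp, left, right, blocks)
  Q <- f4_jack_cov(fb)
  Qi <- tryCatch(solve(Q), error = function(e)
    abort("singular f4 covariance; use fewer or larger blocks"))
  res <- lapply(0:(fb$nl - 1), function(r) {
    fitX <- lowrank_fit(fb$X, Qi, r)
    d <- as.vector(fb$X - fitX)
    stat <- as.numeric(t(d) %*% Qi %*% d)
    dof <- (fb$nl - r) * (fb$nr - r)
    tibble(rank = r, statistic = stat, dof = dof,
           p_value = stats::pchisq(stat, dof, lower.tail = FALSE))
  })
  structure(list(table = bind_rows(res), left = left, right = right,
                 n_sites = fb$n_sites),
            class = "qpwave_result")
}

#' @export
print.qpwave_result <- function(x, ...) {
  cat("<qpwave_result> left:", paste(x$left, collapse = ","), "\n")
  print(x$table)
  invisible(x)
}

# best rank-r approximation of X under the Q^-1 metric (alternating WLS;
# exact for r = 0)
lowrank_fit <- function(X, Qi, r) {
  if (r == 0) return(matrix(0, nrow(X), ncol(X)))
  if (r >= min(dim(X))) return(X)
  sv <- svd(X)
  A <- sv$u[, seq_len(r), drop = FALSE] %*%
    diag(sv$d[seq_len(r)], r, r)
  Bm <- sv$v[, seq_len(r), drop = FALSE]
  obj <- function(Y) { d <- as.vector(X - Y); as.numeric(t(d) %*% Qi %*% d) }
  Y <- A %*% t(Bm)
  best <- obj(Y)
  for (it in 1:50) {
    # minimize over A with B fixed: vec(X - A B') = vec(X) - (B %x% I) vec(A)
    M <- Bm %x% diag(nrow(X))
    A <- matrix(solve(t(M) %*% Qi %*% M, t(M) %*% Qi %*% as.vector(X)),
                nrow(X), r)
    # vec(A B') = (I %x% A) vec(B'), with B' of shape r x ncol(X)
    M2 <- diag(ncol(X)) %x% A
    Bv <- solve(t(M2) %*% Qi %*% M2, t(M2) %*% Qi %*% as.vector(X))
    Bm <- t(matrix(Bv, r, ncol(X)))
    Y2 <- A %*% t(Bm)
    o2 <- obj(Y2)
    if (abs(best - o2) < 1e-10 * (abs(best) + 1)) { Y <- Y2; break }
    Y <- Y2; best <- o2
  }
  Y
}

#' qpAdm admixture-weight estimation
#'
#' Models a target population as a mixture of source populations relative
#' to a set of outgroups ("right" populations): since f4 statistics are
#' linear in the target's allele frequencies, a target
#' `T = sum_i w_i S_i` satisfies
#' `f4(T, base; r_j, r_1) = sum_i w_i f4(S_i, base; r_j, r_1)` for every
#' outgroup contrast.  Weights (summing to 1) are estimated by generalized
#' least squares under the block-jackknife covariance of the residual
#' contrasts; standard errors come from a delete-one-block jackknife of
#' the whole estimation, and nested-model tail probabilities (dropping
#' each source) from qpWave-style rank tests.
#'
#' @param fp a `freq_panel`.
#' @param target target population name.
#' @param sources character vector of >= 2 source names.
#' @param right character vector of outgroups disjoint from
#'   `c(target, sources)`; needs `length(right) - 1 >= length(sources)`.
#' @param blocks block specification (see [f3()]).
#' @return a `qpadm_result`: weights with jackknife SEs, the full-model
#'   rank-test p-value, nested p-values per dropped source, and a
#'   feasibility flag (all weights in `[0, 1]`).
#' @export
qpadm <- function(fp, target, sources, right, blocks = 40) {
  k <- length(sources)
  if (k < 2) abort("need at least 2 sources")
  left <- c(target, sources)
  if (length(intersect(left, right))) abort("left and right sets overlap")
  if (length(right) - 1 < k)
    abort("need at least length(sources) + 1 right populations")
  use <- c(left, right)
  ok <- rowSums(!is.finite(fp$freq[, use, drop = FALSE])) == 0
  ids <- panel_block_ids(fp, blocks)[ok]
  fr <- fp$freq[ok, , drop = FALSE]
  ub <- sort(unique(ids))
  B <- length(ub)
  nr <- length(right) - 1
  # per-block cross-products: rows = (target, sources), cols = right pairs
  d_r <- fr[, right[-1], drop = FALSE] - fr[, right[1]]
  d_l <- fr[, left, drop = FALSE] - fr[, right[1]]
  Cb <- array(0, c(B, k + 1, nr))
  wb <- numeric(B)
  for (bi in seq_len(B)) {
    rows <- ids == ub[bi]
    wb[bi] <- sum(rows)
    Cb[bi, , ] <- crossprod(d_l[rows, , drop = FALSE],
                            d_r[rows, , drop = FALSE])
  }
  solve_w <- function(keep_blocks) {
    Cm <- apply(Cb[keep_blocks, , , drop = FALSE], c(2, 3), sum) /
      sum(wb[keep_blocks])
    y <- Cm[1, ]
    M <- Cm[-1, , drop = FALSE]
    # residual covariance at equal weights, then one GLS refinement
    w <- rep(1 / k, k)
    for (it in 1:3) {
      kb <- which(keep_blocks)
      res_b <- matrix(0, length(kb), nr)
      for (z in seq_along(kb)) {
        bi <- kb[z]
        Mb <- matrix(Cb[bi, -1, ], nrow = k)
        res_b[z, ] <- (Cb[bi, 1, ] - as.numeric(t(Mb) %*% w)) / wb[bi]
      }
      V <- stats::cov(res_b * sqrt(wb[kb] / mean(wb[kb]))) / length(kb)
      V <- V + diag(1e-12 * max(sum(diag(V)), 1e-30), nr)
      Vi <- solve(V)
      # minimize (y - M'w)' Vi (y - M'w) s.t. sum(w) = 1
      A <- M %*% Vi %*% t(M)
      b <- M %*% Vi %*% y
      one <- rep(1, k)
      Ai <- solve(A + diag(1e-14 * max(sum(diag(A)), 1e-30), k))
      lam <- as.numeric((1 - t(one) %*% Ai %*% b) / (t(one) %*% Ai %*% one))
      w <- as.numeric(Ai %*% (b + lam * one))
    }
    resid <- y - as.numeric(t(M) %*% w)
    stat <- as.numeric(t(resid) %*% Vi %*% resid)
    list(w = w, stat = stat)
  }
  all_b <- rep(TRUE, B)
  full <- solve_w(all_b)
  # jackknife SEs for the weights
  loo <- matrix(0, B, k)
  for (bi in seq_len(B)) {
    kb <- all_b; kb[bi] <- FALSE
    loo[bi, ] <- solve_w(kb)$w
  }
  n <- sum(wb); h <- n / wb
  se <- numeric(k)
  for (j in seq_len(k)) {
    theta_j <- B * full$w[j] - sum((1 - wb / n) * loo[, j])
    tau <- h * full$w[j] - (h - 1) * loo[, j]
    se[j] <- sqrt(mean((tau - theta_j)^2 / (h - 1)))
  }
  dof_full <- nr - (k - 1)
  p_full <- stats::pchisq(full$stat, dof_full, lower.tail = FALSE)
  # nested models: drop one source at a time
  nested <- lapply(seq_len(k), function(j) {
    if (k - 1 >= 2) {
      sub <- qpadm(fp, target, sources[-j], right, blocks)
      tibble(dropped = sources[j], p_value = sub$p_full)
    } else {
      # one source left: rank-0 test of target vs that source
      rw <- qpwave_rank(fp, c(target, sources[-j]), right, blocks)
      tibble(dropped = sources[j], p_value = rw$table$p_value[1])
    }
  })
  weights <- tibble(source = sources, weight = full$w, se = se)
  structure(list(target = target, weights = weights, right = right,
                 p_full = p_full, statistic = full$stat, dof = dof_full,
                 nested = bind_rows(nested),
                 feasible = all(full$w >= 0 & full$w <= 1),
                 n_blocks = B, n_sites = n),
            class = "qpadm_result")
}

#' @export
print.qpadm_result <- function(x, ...) {
  cat("<qpadm_result> target:", x$target,
      sprintf("(model p = %.3g%s)", x$p_full,
              if (x$feasible) ", feasible" else ", INFEASIBLE"), "\n")
  print(x$weights)
  invisible(x)
}

#' @export
tidy.qpadm_result <- function(x, ...) {
  mutate(x$weights, target = x$target, p_full = x$p_full,
         feasible = x$feasible)
}

#' @export
glance.qpadm_result <- function(x, ...) {
  tibble(target = x$target, n_sources = nrow(x$weights),
         statistic = x$statistic, dof = x$dof, p_value = x$p_full,
         feasible = x$feasible, n_blocks = x$n_blocks, n_sites = x$n_sites)
}
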