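#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact two-sided test for a biallelic site from diploid genotype counts,
#' computed by enumerating the conditional distribution of the heterozygote
#' count given the allele counts (the standard exact HWE recurrence).  The
#' p-value is the total probability of all heterozygote configurations no
#' more probable than the observed one.
#'
#' @param n_het number of heterozygous individuals.
#' @param n_hom_ref,n_hom_alt homozygote counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_het, n_hom_ref, n_hom_alt) {
  n <- n_het + n_hom_ref + n_hom_alt
  if (n == 0) return(1)
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0) return(1)
  # possible heterozygote counts share the parity of the rare-allele count
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # unnormalized probabilities via the ratio recurrence
  lp <- numeric(length(hets))
  for (i in seq_along(lp)[-1]) {
    h <- hets[i]
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    # P(h) / P(h-2) = 4 * (hom_r + 1) * (hom_c + 1) / (h * (h - 1))
    lp[i] <- lp[i - 1] + log(4) + log(hom_r + 1) + log(hom_c + 1) -
      log(h) - log(h - 1)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  if (is.na(obs)) abort("heterozygote count inconsistent with allele counts")
  sum(p[p <= p[obs] * (1 + 1e-12)])
}
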