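test_that("VCF round trip preserves calls, polarity and metadata", {
  g <- toy_geno()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(g, path, "vcf")
  pm <- setNames(g$samples$pop, g$samples$sample_id)
  g2 <- read_genotypes(path, "vcf", pop_map = pm)
  expect_identical(unname(g2$calls), unname(g$calls))
  expect_identical(g2$variants$aa, g$variants$aa)
  expect_identical(g2$variants$pos, g$variants$pos)
  expect_identical(g2$samples$pop, g$samples$pop)
})

test_that("EIGENSTRAT round trip preserves calls and ancestral column", {
  g <- random_geno(seed = 7)
  g$variants$aa[3] <- NA
  prefix <- file.path(withr::local_tempdir(), "panel")
  write_genotypes(g, prefix, "eigenstrat")
  g2 <- read_genotypes(prefix, "eigenstrat")
  expect_identical(unname(g2$calls), unname(g$calls))
  expect_identical(g2$variants$aa, g$variants$aa)
  expect_identical(g2$samples$pop, g$samples$pop)
})

test_that("empty VCF yields a zero-site matrix", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"AA\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "s1", sep = "\t")), path)
  g <- read_genotypes(path, "vcf")
  expect_equal(n_sites(g), 0)
  expect_equal(n_samples(g), 1)
})

test_that("derived counts follow the ancestral allele, not REF", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"AA\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1"), collapse = "\t"),
               "1\t10\t.\tA\tG\t.\tPASS\tAA=A\tGT\t1/1",
               "1\t20\t.\tA\tG\t.\tPASS\tAA=G\tGT\t1/1"), path)
  g <- read_genotypes(path, "vcf")
  expect_equal(g$calls[1, 1], 2L)  # AA=REF: 1/1 carries 2 derived copies
  expect_equal(g$calls[1, 2], 0L)  # AA=ALT: 1/1 is ancestral-homozygous
})

test_that("multi-allelic and indel records are dropped with a message", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"AA\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1"), collapse = "\t"),
               "1\t10\t.\tA\tG,T\t.\tPASS\tAA=A\tGT\t1/1",
               "1\t20\t.\tAT\tA\t.\tPASS\tAA=A\tGT\t0/1",
               "1\t30\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0/1"), path)
  expect_message(g <- read_genotypes(path, "vcf"), "dropped")
  expect_equal(n_sites(g), 1)
  expect_equal(g$variants$pos, 30L)
})

test_that("the five SFS site filters each remove their construction", {
  # five sites, each violating exactly one criterion
  n <- 40  # 20 diploids per population: enough for the exact test to
           # reach p < 1e-4 on an all-heterozygote site
  samples <- tibble::tibble(sample_id = paste0("s", 1:n),
                            pop = rep(c("A", "B"), each = n / 2))
  mk_calls <- function(...) do.call(cbind, list(...))
  hwe_violator <- rep(1L, n)  # every individual heterozygous
  clean <- c(rep(0L, n - 2), 1L, 1L)
  missing1 <- c(NA, rep(0L, n - 2), 1L)
  calls <- mk_calls(missing1, hwe_violator, clean, clean, clean)
  variants <- tibble::tibble(
    chrom = "1", pos = c(10L, 20L, 30L, 40L, 50L),
    ref = "A", alt = "G",
    aa = c("A", "A", "A", "A", NA),
    cpg = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    coding = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  g <- geno_matrix(samples, variants, calls)
  gf <- apply_sfs_filters(g, hwe_alpha = 1e-4)
  rep_tab <- filter_report(gf)
  expect_equal(n_sites(gf), 0)
  expect_equal(rep_tab$n_removed[rep_tab$criterion == "missing"], 1)
  expect_equal(rep_tab$n_removed[rep_tab$criterion == "hwe"], 1)
  expect_equal(rep_tab$n_removed[rep_tab$criterion == "cpg"], 1)
  expect_equal(rep_tab$n_removed[rep_tab$criterion == "coding"], 1)
  expect_equal(rep_tab$n_removed[rep_tab$criterion == "no_ancestral"], 1)
  # disjoint single-criterion fixtures: removals sum to sites removed
  expect_equal(sum(rep_tab$n_removed), n_sites(g) - n_sites(gf))
})

test_that("filtering is idempotent and clean input passes unchanged", {
  g <- random_geno(seed = 11)
  g1 <- apply_sfs_filters(g)
  g2 <- apply_sfs_filters(g1)
  expect_identical(g1$calls, g2$calls)
  expect_identical(g1$variants$pos, g2$variants$pos)
  expect_equal(sum(filter_report(g2)$n_removed), 0)
})

test_that("BED masks use half-open 0-based coordinates", {
  g <- toy_geno()
  g$calls[is.na(g$calls)] <- 0L
  # interval [100, 200) covers pos 101..200 -> site at pos 200 inside,
  # site at pos 100 outside
  bed <- tibble::tibble(chrom = "1", start = 100, end = 200)
  gf <- apply_sfs_filters(g, cpg_mask = bed)
  expect_false(200L %in% gf$variants$pos)
  expect_true(100L %in% gf$variants$pos)
})

test_that("allele frequencies match brute-force per-site counting", {
  g <- random_geno(n_per_pop = 4, n_sites = 30, seed = 5)
  panel <- population_panel(c("A", "B"), c(8, 8))
  fp <- allele_frequencies(g, panel)
  for (s in c(1, 7, 30)) {
    for (p in c("A", "B")) {
      rows <- which(g$samples$pop == p)
      expect_equal(unname(fp$freq[s, p]),
                   sum(g$calls[rows, s]) / (2 * length(rows)))
    }
  }
  # 2 diploids with counts {0, 2} -> frequency 0.5
  fp1 <- freq_panel(matrix(0.5, 1, 1))
  expect_equal(unname(fp1$freq[1, 1]), 0.5)
})

test_that("all-missing population at a site is flagged unavailable", {
  g <- toy_geno()
  g$calls[1:3, 8] <- NA  # population A fully missing at site 8
  panel <- population_panel(c("A", "B"), c(6, 6))
  fp <- allele_frequencies(g, panel)
  expect_true(is.na(fp$freq[8, "A"]))
  expect_equal(unname(fp$n_obs[8, "A"]), 0L)
  expect_false(is.na(fp$freq[8, "B"]))
})

test_that("unassigned samples raise an error", {
  g <- toy_geno()
  panel <- population_panel("A", 6)
  expect_error(allele_frequencies(g, panel), "outside the panel")
})

test_that("pairwise mismatch rate matches a brute-force site loop", {
  g <- random_geno(n_per_pop = 3, n_sites = 40, seed = 13)
  g$calls[2, 5] <- NA
  r <- pairwise_mismatch_rate(g, 1, 2)
  both <- !is.na(g$calls[1, ]) & !is.na(g$calls[2, ])
  expect_equal(r, mean(g$calls[1, both] != g$calls[2, both]))
  expect_equal(pairwise_mismatch_rate(g, 3, 3), 0)
})

test_that("complete mismatch and missing-overlap edge cases", {
  samples <- tibble::tibble(sample_id = c("x", "y"), pop = "A")
  variants <- tibble::tibble(chrom = "1", pos = c(1L, 2L), ref = "A",
                             alt = "G", aa = "A")
  g <- geno_matrix(samples, variants, matrix(c(0L, 2L, 0L, 2L), 2, 2))
  expect_equal(pairwise_mismatch_rate(g, "x", "y"), 1)
  g$calls[1, ] <- NA
  expect_error(pairwise_mismatch_rate(g, "x", "y"), "non-missing")
})

test_that("exact HWE test matches brute-force enumeration", {
  # enumeration oracle: probability of each het count given allele counts
  brute <- function(n_het, n_ref, n_alt) {
    n <- n_het + n_ref + n_alt
    n_a <- 2 * n_ref + n_het
    hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
    pr <- sapply(hets, function(h) {
      hom_r <- (n_a - h) / 2
      hom_c <- n - h - hom_r
      if (hom_r < 0 || hom_c < 0) return(0)
      exp(lfactorial(n) - lfactorial(hom_r) - lfactorial(hom_c) -
            lfactorial(h) + h * log(2) +
            lfactorial(n_a) + lfactorial(2 * n - n_a) - lfactorial(2 * n))
    })
    pr <- pr / sum(pr)
    obs <- pr[match(n_het, hets)]
    sum(pr[pr <= obs * (1 + 1e-12)])
  }
  cases <- list(c(1, 2, 2), c(5, 0, 0), c(2, 4, 4), c(0, 5, 5), c(3, 1, 6))
  for (cs in cases) {
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 brute(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  }
  expect_equal(hwe_exact_p(0, 10, 0), 1)
})
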