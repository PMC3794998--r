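test_that("heterozygosity summaries follow the unbiased estimator", {
  # n=2, two homozygotes for different alleles: H_o = 0,
  # H_e = (4/3)(1 - 2 (1/2)^2) = 2/3
  ds <- make_ds(list(g1(12, 12), g1(34, 34)), c("s", "s"))
  het <- heterozygosity(ds)
  expect_equal(het$H_o, 0)
  expect_equal(het$H_e, 2 / 3)
  expect_equal(het$n_alleles, 2L)
  # n=2, four alleles at frequency 1/4: H_e = (4/3)(1 - 4 (1/4)^2) = 1
  ds4 <- make_ds(list(g1(1, 2), g1(3, 4)), c("s", "s"))
  het4 <- heterozygosity(ds4)
  expect_equal(het4$H_e, 1)
  expect_equal(het4$H_o, 1)
  expect_equal(het4$n_alleles, 4L)
  # monomorphic locus
  ds0 <- make_ds(list(g1(2, 2), g1(2, 2), g1(2, 2)), rep("s", 3))
  h0 <- heterozygosity(ds0)
  expect_equal(h0$H_o, 0)
  expect_equal(h0$H_e, 0)
  expect_false(h0$polymorphic)
  # all heterozygous
  ds1 <- make_ds(list(g1(1, 2), g1(1, 2), g1(2, 1)), rep("s", 3))
  expect_equal(heterozygosity(ds1)$H_o, 1)
  # site means cover polymorphic loci only
  ds2 <- make_ds(list(rbind(c(1, 2), c(5, 5)), rbind(c(1, 1), c(5, 5))),
                 c("s", "s"))
  sm <- heterozygosity_site_means(heterozygosity(ds2))
  expect_equal(sm$n_polymorphic_loci, 1)
  expect_equal(sm$mean_H_o, 0.5)
})

test_that("H_e is unbiased against the true allele frequencies under HWE", {
  p <- c(0.5, 0.3, 0.2)
  n <- 40
  est <- withr::with_seed(99, vapply(1:300, function(r) {
    a <- matrix(sample.int(3, 2 * n, replace = TRUE, prob = p), ncol = 2)
    calls <- array(a, c(n, 1, 2))
    heterozygosity(genotype_dataset(seq_len(n), rep("s", n), "L1", calls))$H_e
  }, numeric(1)))
  truth <- 1 - sum(p^2)
  expect_lt(abs(mean(est) - truth), 2 * sd(est) / sqrt(length(est)))
})

test_that("the Hardy-Weinberg Monte-Carlo exact test matches full enumeration", {
  # n = 3, two alleles: enumerate all 720 orderings of the allele pool
  ds <- make_ds(list(g1(1, 1), g1(1, 2), g1(2, 2)), rep("s", 3))
  pool <- c(1, 1, 1, 2, 2, 2)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  obs_lp <- sealmix:::log_genotype_array_prob(cbind(c(1, 1, 2), c(1, 2, 2)))
  lps <- vapply(perms(pool), function(o) {
    sealmix:::log_genotype_array_prob(cbind(o[c(1, 3, 5)], o[c(2, 4, 6)]))
  }, numeric(1))
  p_exact <- mean(lps <= obs_lp + 1e-9)
  res <- hwe_test(ds, "s", "L1", n_perm = 999, seed = 7)
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(res$p - p_exact), 2 * se + 1 / 1000)
})

test_that("extreme heterozygote excess is rejected and edge cases return NA", {
  ds <- make_ds(replicate(50, g1(1, 2), simplify = FALSE), rep("s", 50))
  res <- hwe_test(ds, "s", "L1", n_perm = 999, seed = 3)
  expect_lt(res$p, 0.01)
  # heterozygote excess means the homozygote-excess tail is not extreme
  expect_gt(res$p_homozygote_excess, 0.5)
  # monomorphic -> NA; determinism under the seed
  ds0 <- make_ds(replicate(5, g1(1, 1), simplify = FALSE), rep("s", 5))
  expect_true(is.na(hwe_test(ds0, "s", "L1", seed = 1)$p))
  expect_identical(hwe_test(ds, "s", "L1", n_perm = 199, seed = 11)$p,
                   hwe_test(ds, "s", "L1", n_perm = 199, seed = 11)$p)
})

test_that("the linkage test finds perfect dependence and honors the p floor", {
  set.seed(13)
  geno <- sample(list(g1(1, 1), g1(1, 2), g1(2, 2)), 30, replace = TRUE)
  ds <- make_ds(lapply(geno, function(g) rbind(g, g)), rep("s", 30))
  res <- ld_test(ds, "s", c("L1", "L2"), n_perm = 199, seed = 5)
  # a locus paired with its own copy: minimal achievable p up to ties
  expect_lt(res$p, 0.05)
  expect_gte(res$p, 1 / 200)
  # monomorphic partner -> NA
  ds2 <- make_ds(lapply(geno, function(g) rbind(g, g1(1, 1))), rep("s", 30))
  expect_true(is.na(ld_test(ds2, "s", c("L1", "L2"), seed = 1)$p))
})

test_that("Bonferroni-adjusted levels reproduce the reporting convention", {
  expect_equal(as.numeric(bonferroni_alpha(0.05, 9 * 11, 1)), 0.0005)
  expect_equal(as.numeric(bonferroni_alpha(0.05, 36 * 11, 1)), 0.0001)
  expect_equal(as.numeric(bonferroni_alpha(0.05, 1)), 0.05)
  expect_equal(attr(bonferroni_alpha(0.05, 99, 1), "unrounded"), 0.05 / 99)
})

test_that("rarefaction is exact at full sample size and bounded at N = 1", {
  sp <- island_model_spec(2, c(8, 12), 3, c(4, 7, 10), target_fst = 0.05,
                          seed = 17)
  ds <- simulate_island_genotypes(sp)
  rc <- rarefied_allelic_richness(ds, c(1, 8), n_reps = 50, seed = 1)
  full <- rc[rc$unit == "site01" & rc$N == 8, ]
  expect_equal(full$sd_richness, 0)
  expect_equal(full$mean_richness, sealmix:::mean_richness(ds$calls, 1:8))
  n1 <- rc[rc$N == 1, ]
  expect_true(all(n1$mean_richness >= 1 & n1$mean_richness <= 2))
  # monotone in N
  rc2 <- rarefied_allelic_richness(ds, c(2, 4, 6, 8), n_reps = 200, seed = 2)
  for (u in unique(rc2$unit)) {
    m <- rc2$mean_richness[rc2$unit == u]
    expect_true(all(diff(m) > -1e-9))
  }
  # N = 10 exceeds site01 (n = 8) but not site02 (n = 12)
  expect_warning(rc3 <- rarefied_allelic_richness(ds, 10, n_reps = 5, seed = 1),
                 "exceeds")
  expect_equal(rc3$unit, "site02")
})

test_that("subsampled richness agrees with the hypergeometric closed form", {
  # fixed-seed random pairing of a known gene pool; no missing data
  n <- 20
  gene_counts <- list(c(14, 10, 8, 4, 2, 2), c(20, 12, 6, 2))
  calls <- array(NA_integer_, c(n, 2, 2))
  withr::with_seed(23, for (l in 1:2) {
    pool <- sample(rep(seq_along(gene_counts[[l]]), gene_counts[[l]]))
    calls[, l, ] <- matrix(pool, ncol = 2)
  })
  ds <- genotype_dataset(seq_len(n), rep("s", n), c("L1", "L2"), calls)
  closed_form <- function(N) {
    mean(vapply(gene_counts, function(cs) {
      sum(1 - choose(2 * n - cs, 2 * N) / choose(2 * n, 2 * N))
    }, numeric(1)))
  }
  rc <- rarefied_allelic_richness(ds, c(5, 10), n_reps = 400, seed = 4)
  for (N in c(5, 10)) {
    row <- rc[rc$N == N, ]
    se <- row$sd_richness / sqrt(row$n_reps)
    expect_lt(abs(row$mean_richness - closed_form(N)), 3 * se + 0.02)
  }
})

test_that("the richness difference test is calibrated against itself", {
  sp <- island_model_spec(2, 15, 3, 8, target_fst = 0, seed = 31)
  ds <- simulate_island_genotypes(sp)
  # comparing a unit against a same-distribution unit: p not extreme
  res <- richness_difference_test(ds, c("site01", "site02"), N = 10,
                                  n_reps = 40, n_perm = 59, seed = 9)
  expect_gt(res$p, 0.05)
  expect_gte(res$p, 1 / 60)
})

test_that("haplotype tallies key on exact identity with listwise deletion", {
  aln <- seq_alignment(c("a", "b", "c", "d"),
                       c("X", "X", "Y", "Y"),
                       c("ACGTACGT", "ACGTACGT", "ACGAACGT", "ACGTACGT"))
  hf <- haplotype_frequencies(aln)
  expect_equal(nrow(hf$haplotypes), 2)
  expect_equal(unname(hf$counts["X", "H01"]), 2)
  expect_equal(unname(hf$frequencies["Y", "H01"]), 0.5)
  # positions with N/- anywhere are excluded for everyone
  aln2 <- seq_alignment(c("a", "b"), c("X", "X"), c("ACGTNCGT", "ACGAACGT"))
  hf2 <- haplotype_frequencies(aln2)
  expect_equal(nrow(hf2$haplotypes), 2)   # still differ at position 4
  aln3 <- seq_alignment(c("a", "b"), c("X", "X"), c("ACGNACGT", "ACGAACGT"))
  expect_equal(nrow(haplotype_frequencies(aln3)$haplotypes), 1)
  # invariance under reordering
  hf_r <- haplotype_frequencies(
    seq_alignment(aln$ids[4:1], aln$sites[4:1], aln$sequences[4:1]))
  expect_equal(nrow(hf_r$haplotypes), 2)
  expect_equal(sort(hf_r$haplotypes$count), sort(hf$haplotypes$count))
})

test_that("the one-mismatch duplicate screen counts allele differences", {
  base <- matrix(rep(c(1L, 2L), each = 9), ncol = 2)   # 9 loci, all het 1/2
  one_off <- base; one_off[4, ] <- c(1L, 1L)           # ij -> ii: 1 mismatch
  two_off <- base; two_off[4, ] <- c(3L, 3L)           # ij -> kk: 2 mismatches
  ds <- make_ds(list(base, base, one_off, two_off), rep("s", 4),
                ids = c("dup1", "dup2", "near", "far"))
  fl <- find_duplicate_genotypes(ds)
  key <- paste(fl$id_a, fl$id_b)
  expect_true("dup1 dup2" %in% key)
  expect_equal(fl$mismatches[key == "dup1 dup2"], 0L)
  expect_true(all(c("dup1 near", "dup2 near") %in% key))
  expect_equal(fl$mismatches[key == "dup1 near"], 1L)
  expect_false(any(grepl("far", key)))                 # 2 mismatches: not flagged
  # resolution keeps the first-seen copy
  red <- remove_duplicate_genotypes(ds)
  expect_setequal(red$removed, c("dup2", "near"))
  expect_equal(red$dataset$ids, c("dup1", "far"))
})
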