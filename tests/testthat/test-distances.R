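test_that("the single-locus genotype distance scheme gives 0,1,2,3,4", {
  expect_equal(genotype_distance(g1(1, 1), g1(1, 1)), 0L)   # (ii, ii)
  expect_equal(genotype_distance(g1(1, 2), g1(1, 2)), 0L)   # (ij, ij)
  expect_equal(genotype_distance(g1(1, 1), g1(1, 2)), 1L)   # (ii, ij)
  expect_equal(genotype_distance(g1(1, 2), g1(1, 3)), 1L)   # (ij, ik)
  expect_equal(genotype_distance(g1(1, 2), g1(3, 4)), 2L)   # (ij, kl)
  expect_equal(genotype_distance(g1(1, 1), g1(2, 3)), 3L)   # (ii, jk)
  expect_equal(genotype_distance(g1(1, 1), g1(2, 2)), 4L)   # (ii, jj)
  # allele order within a genotype is immaterial
  expect_equal(genotype_distance(g1(2, 1), g1(3, 1)), 1L)
})

test_that("multi-locus genotype distance sums single-locus values and skips missing", {
  a <- rbind(c(1, 1), c(1, 2), c(NA, NA))
  b <- rbind(c(1, 2), c(3, 4), c(5, 5))
  expect_equal(genotype_distance(a, b), 1L + 2L)   # (ii,ij)=1 + (ij,kl)=2
  expect_error(genotype_distance(rbind(c(NA, NA)), rbind(c(1, 1))), "coverage")
})

test_that("allele-count-difference distance counts non-shared alleles", {
  expect_equal(allele_count_diff_distance(g1(1, 2), g1(1, 2)), 0L)
  expect_equal(allele_count_diff_distance(g1(1, 2), g1(1, 3)), 1L)
  expect_equal(allele_count_diff_distance(g1(1, 1), g1(2, 2)), 2L)
  expect_equal(allele_count_diff_distance(g1(1, 1), g1(1, 2)), 1L)
  a <- rbind(c(1, 2), c(1, 1))
  b <- rbind(c(1, 3), c(2, 2))
  expect_equal(allele_count_diff_distance(a, b), 1L + 2L)
})

test_that("integer genotype metrics are symmetric metrics on random genotypes", {
  set.seed(11)
  rand_geno <- function() matrix(sample.int(4, 6, replace = TRUE), ncol = 2)
  for (rep in 1:40) {
    x <- rand_geno(); y <- rand_geno(); z <- rand_geno()
    for (fn in list(genotype_distance, allele_count_diff_distance)) {
      expect_identical(fn(x, y), fn(y, x))
      expect_identical(fn(x, x), 0L)
      expect_gte(fn(x, z) + fn(z, y), fn(x, y))   # triangle inequality
    }
  }
})

test_that("TN93+gamma distance matches an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(21)
  base <- c("a", "c", "g", "t")
  for (n_mut in c(10, 40, 90)) {
    s1 <- sample(base, 400, replace = TRUE)
    s2 <- s1
    idx <- sample(400, n_mut)
    for (p in idx) s2[p] <- sample(setdiff(base, s2[p]), 1)
    m <- rbind(s1, s2)
    rownames(m) <- c("a", "b")
    for (alpha in c(0.164, 0.25103, 1)) {
      ours <- tn93_gamma_distance(paste(s1, collapse = ""),
                                  paste(s2, collapse = ""), alpha)
      ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "TN93",
                                      gamma = alpha))
      expect_equal(ours, ref, tolerance = 1e-10)
    }
    # uncorrected limit: alpha -> Inf converges to plain TN93
    ref0 <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "TN93"))
    expect_equal(tn93_gamma_distance(paste(s1, collapse = ""),
                                     paste(s2, collapse = ""), 1e6),
                 ref0, tolerance = 1e-3)
    expect_equal(tn93_gamma_distance(paste(s1, collapse = ""),
                                     paste(s2, collapse = ""), Inf),
                 ref0, tolerance = 1e-12)
  }
})

test_that("TN93 handles identity, pairwise deletion and saturation", {
  s <- strrep("ACGT", 25)
  expect_equal(tn93_gamma_distance(s, s, 0.25), 0)
  # N and gap positions are excluded pairwise
  s2 <- paste0("N-", substr(s, 3, 100))
  expect_equal(tn93_gamma_distance(s, s2, 0.25), 0)
  expect_error(tn93_gamma_distance("NNNN", "ACGT", 0.25), "coverage")
  # maximally diverged pair saturates; the cap option substitutes a value
  a <- strrep("AAAACCCCGGGGTTTT", 5)
  b <- strrep("CCCCAAAATTTTGGGG", 5)
  expect_error(tn93_gamma_distance(a, b, 0.25), "saturation")
  expect_equal(tn93_gamma_distance(a, b, 0.25, cap_saturated = 5), 5)
})

test_that("TN93 is monotone in divergence at fixed composition", {
  set.seed(31)
  s1 <- sample(c("A", "C", "G", "T"), 600, replace = TRUE)
  prev <- -1
  s2 <- s1
  order_mut <- sample(600)
  for (k in c(5, 20, 50, 100)) {
    s2k <- s1
    for (p in order_mut[1:k]) s2k[p] <- sample(setdiff(c("A", "C", "G", "T"), s1[p]), 1)
    d <- tn93_gamma_distance(paste(s1, collapse = ""), paste(s2k, collapse = ""), 0.25103)
    expect_gt(d, prev)
    prev <- d
  }
})

test_that("pairwise sequence distances agree with single-pair recomputation", {
  aln <- simulate_mtdna_haplotypes(c(A = 4, B = 3), shared_pool = 3,
                                   private_pool = 1, divergence = 4,
                                   seq_length = 200, seed = 5)
  dm <- pairwise_sequence_distances(aln, alpha = 0.25103)
  expect_equal(dm$metric, "tn93_gamma")
  expect_equal(dm$parameters$alpha, 0.25103)
  for (i in c(1, 3)) {
    for (j in c(2, 5)) {
      expect_equal(dm$values[i, j],
                   tn93_gamma_distance(aln$sequences[i], aln$sequences[j], 0.25103))
    }
  }
  expect_true(isSymmetric(dm$values))
  expect_equal(diag(dm$values), setNames(rep(0, 7), aln$ids))

  # identical sequences give a zero matrix
  aln0 <- seq_alignment(c("a", "b", "c"), rep("s", 3), rep(strrep("ACGT", 30), 3))
  expect_true(all(pairwise_sequence_distances(aln0, 0.25)$values == 0))

  # permuting input order permutes rows/columns consistently
  perm <- c(3, 1, 2, 7, 5, 6, 4)
  aln_p <- seq_alignment(aln$ids[perm], aln$sites[perm], aln$sequences[perm])
  dm_p <- pairwise_sequence_distances(aln_p, alpha = 0.25103)
  expect_equal(dm_p$values, dm$values[perm, perm])
})

test_that("distance matrices validate and write with metadata", {
  expect_error(dist_matrix(matrix(c(0, 1, 2, 0), 2), c("a", "b"), "m"),
               "symmetric")
  V <- matrix(c(0, 1, 1, 0), 2)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_dist_csv(dist_matrix(V, c("a", "b"), "tn93_gamma", list(alpha = 0.164)), tf)
  lines <- readLines(tf)
  expect_match(lines[1], "metric=tn93_gamma")
  expect_match(lines[1], "alpha=0.164")
})
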