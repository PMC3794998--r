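test_that("Weir-Cockerham theta matches hand-evaluated variance components", {
  # 2 sites, 1 locus, n = (4, 4)
  genos_a <- list(g1(1, 1), g1(1, 2), g1(2, 2), g1(1, 1))
  genos_b <- list(g1(2, 2), g1(2, 2), g1(1, 2), g1(2, 2))
  ds <- make_ds(c(genos_a, genos_b), rep(c("A", "B"), each = 4))

  # independent scalar evaluation of the published a, b, c formulas
  r <- 2; n_i <- c(4, 4); nbar <- 4
  n_c <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  hand <- c(a = 0, b = 0, c = 0)
  for (al in 1:2) {
    cnt_a <- sum(vapply(genos_a, function(g) sum(g == al), numeric(1)))
    cnt_b <- sum(vapply(genos_b, function(g) sum(g == al), numeric(1)))
    p_i <- c(cnt_a, cnt_b) / (2 * n_i)
    h_i <- c(mean(vapply(genos_a, function(g) g[1] != g[2] && al %in% g, logical(1))),
             mean(vapply(genos_b, function(g) g[1] != g[2] && al %in% g, logical(1))))
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / n_c) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    hand <- hand + c(a = a, b = b, c = hbar / 2)
  }
  res <- weir_cockerham_fst(ds)
  expect_equal(res$theta, unname(hand["a"] / sum(hand)), tolerance = 1e-12)
  comp <- res$components
  expect_equal(comp$a, unname(hand["a"]), tolerance = 1e-12)
  expect_equal(comp$b, unname(hand["b"]), tolerance = 1e-12)
  expect_equal(comp$c, unname(hand["c"]), tolerance = 1e-12)
})

test_that("theta is 1 under complete fixation and ~0 for duplicated sites", {
  expect_equal(weir_cockerham_fst(fixed_difference_ds())$theta, 1)
  set.seed(41)
  genos <- replicate(12, matrix(sample.int(5, 6, TRUE), ncol = 2),
                     simplify = FALSE)
  dup <- make_ds(c(genos, genos), rep(c("A", "B"), each = 12))
  expect_lte(weir_cockerham_fst(dup)$theta, 1e-12)
  # no shared polymorphic locus -> NA with diagnostic
  mono <- make_ds(list(g1(1, 1), g1(1, 1), g1(1, 1), g1(1, 1)),
                  rep(c("A", "B"), each = 2))
  expect_true(is.na(weir_cockerham_fst(mono)$theta))
})

test_that("theta handles missing genotypes by per-locus deletion", {
  genos <- c(list(rbind(c(1, 1), c(NA, NA)), rbind(c(1, 2), c(3, 3)),
                  rbind(c(1, 1), c(3, 4))),
             list(rbind(c(2, 2), c(3, 3)), rbind(c(2, 2), c(4, 4)),
                  rbind(c(1, 2), c(NA, NA))))
  ds <- make_ds(genos, rep(c("A", "B"), each = 3))
  res <- weir_cockerham_fst(ds)
  expect_true(is.finite(res$theta))
  expect_equal(res$n_loci_used, 2)
})

test_that("the pairwise F_ST permutation test separates fixed sites", {
  ds <- fixed_difference_ds(n_per_site = 10, n_loci = 3)
  res <- fst_permutation_test(ds, c("A", "B"), n_perm = 999, seed = 2)
  expect_equal(res$statistic, 1)
  # only the identity/complement partitions reach theta = 1
  expect_equal(res$p, 1 / 1000)
  expect_identical(res$p,
                   fst_permutation_test(ds, c("A", "B"), n_perm = 999, seed = 2)$p)
})

test_that("AMOVA components match brute-force SS evaluation on a 3-site toy", {
  # 6 individuals in 3 sites of 2; integer distances
  set.seed(47)
  V <- matrix(0, 6, 6)
  V[upper.tri(V)] <- sample(1:9, 15, replace = TRUE)
  V <- V + t(V)
  labels <- rep(c("A", "B", "C"), each = 2)
  dm <- dist_matrix(V, paste0("i", 1:6), "toy")
  res <- amova(dm, labels, n_perm = 199, seed = 5)

  # brute force: explicit pair enumeration of the squared-distance SS
  N <- 6; k <- 3
  ss_tot <- 0
  for (i in 1:5) for (j in (i + 1):6) ss_tot <- ss_tot + V[i, j]^2
  ss_tot <- ss_tot / N
  ss_win <- 0
  for (s in unique(labels)) {
    idx <- which(labels == s)
    ss_win <- ss_win + V[idx[1], idx[2]]^2 / length(idx)
  }
  ss_amg <- ss_tot - ss_win
  sw <- ss_win / (N - k)
  n0 <- (N - sum(table(labels)^2) / N) / (k - 1)
  sa <- (ss_amg / (k - 1) - sw) / n0
  expect_equal(res$table$SS, c(ss_amg, ss_win), tolerance = 1e-12)
  expect_equal(res$table$sigma2, c(sa, sw), tolerance = 1e-12)
  expect_equal(res$phi_st, sa / (sa + sw), tolerance = 1e-12)
  expect_equal(sum(res$table$percent), 100, tolerance = 1e-9)
  expect_gte(res$p, 1 / 200)
})

test_that("AMOVA handles degenerate and saturated structures", {
  V0 <- matrix(0, 6, 6)
  dm0 <- dist_matrix(V0, paste0("i", 1:6), "toy")
  res0 <- amova(dm0, rep(c("A", "B", "C"), each = 2), n_perm = 99, seed = 1)
  expect_true(res0$degenerate)
  expect_equal(res0$table$percent, c(0, 100))
  expect_true(is.na(res0$phi_st))
  expect_equal(res0$p, 1)

  # zero within, positive between: Phi_ST -> 1
  V1 <- matrix(4, 4, 4); diag(V1) <- 0
  V1[1, 2] <- V1[2, 1] <- 0; V1[3, 4] <- V1[4, 3] <- 0
  dm1 <- dist_matrix(V1, paste0("i", 1:4), "toy")
  res1 <- amova(dm1, rep(c("A", "B"), each = 2), n_perm = 99, seed = 1)
  expect_equal(res1$phi_st, 1)

  # singleton sites are excluded with a warning
  expect_warning(
    res2 <- amova(dist_matrix(matrix(1, 5, 5) - diag(5), paste0("i", 1:5), "t"),
                  c("A", "A", "B", "B", "C"), n_perm = 9, seed = 1),
    "singleton")
  expect_equal(res2$excluded, "i5")
})

test_that("average pairwise differences match hand enumeration", {
  # two sites of 2 with constructed integer distances
  V <- matrix(0, 4, 4)
  V[1, 2] <- 3; V[3, 4] <- 5
  V[1, 3] <- 2; V[1, 4] <- 4; V[2, 3] <- 6; V[2, 4] <- 8
  V <- V + t(V)
  dm <- dist_matrix(V, paste0("i", 1:4), "toy")
  apd <- avg_pairwise_differences(dm, c("A", "A", "B", "B"))
  expect_equal(unname(apd$within), c(3, 5))
  expect_equal(apd$between["A", "B"], mean(c(2, 4, 6, 8)))
  expect_equal(apd$between["A", "B"], apd$between["B", "A"])
  # identical individuals everywhere -> all zeros
  apd0 <- avg_pairwise_differences(
    dist_matrix(matrix(0, 4, 4), paste0("i", 1:4), "t"), c("A", "A", "B", "B"))
  expect_true(all(apd0$within == 0))
  # singleton within is NA
  apd1 <- avg_pairwise_differences(dm, c("A", "A", "A", "B"))
  expect_true(is.na(apd1$within["B"]))
})

test_that("theta and distance-based Phi_ST order simulated drift levels alike", {
  levels <- c(0.02, 0.08, 0.2, 0.35, 0.5)
  theta <- numeric(5); phi <- numeric(5)
  for (i in seq_along(levels)) {
    ds <- simulate_island_genotypes(
      island_model_spec(2, 20, 6, 8, target_fst = levels[i], seed = 600 + i))
    theta[i] <- weir_cockerham_fst(ds)$theta
    dm <- pairwise_genotype_distances(ds, "allele_count_diff")
    phi[i] <- amova(dm, ds$sites, n_perm = 0, seed = 1)$phi_st
  }
  expect_gt(cor(theta, phi, method = "spearman"), 0.9)
  expect_true(all(sign(theta) == sign(phi)))
})
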