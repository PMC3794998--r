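# helper: integer allele matrix (n x 2) for one site x locus, missing dropped
site_locus_alleles <- function(ds, site, locus) {
  k <- which(ds$sites == site)
  l <- match(locus, ds$loci)
  g <- ds$calls[k, l, , drop = TRUE]
  if (is.null(dim(g))) g <- matrix(g, ncol = 2)
  g[!is.na(g[, 1]), , drop = FALSE]
}

#' Per site x locus heterozygosity summary
#'
#' Observed heterozygosity `H_o` is the fraction of heterozygous individuals
#' among those genotyped; expected heterozygosity uses Nei's unbiased
#' estimator `H_e = (2n/(2n-1)) (1 - sum p_k^2)`.  A locus is polymorphic
#' within a site when >= 2 alleles are observed there (no frequency
#' threshold).
#'
#' @param ds a [genotype_dataset()]
#' @return data frame with columns `site, locus, n, n_alleles, H_o, H_e,
#'   polymorphic`; cells with no genotyped individuals get `n = 0` and `NA`
#'   statistics
#' @export
heterozygosity <- function(ds) {
  out <- expand.grid(site = unique(ds$sites), locus = ds$loci,
                     stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(out)), function(r) {
    g <- site_locus_alleles(ds, out$site[r], out$locus[r])
    n <- nrow(g)
    if (n == 0) return(data.frame(n = 0L, n_alleles = 0L, H_o = NA_real_,
                                  H_e = NA_real_, polymorphic = NA))
    p <- as.numeric(table(c(g[, 1], g[, 2]))) / (2 * n)
    Ho <- mean(g[, 1] != g[, 2])
    He <- if (n >= 2) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else NA_real_
    data.frame(n = n, n_alleles = length(p), H_o = Ho, H_e = He,
               polymorphic = length(p) >= 2)
  })
  cbind(out, do.call(rbind, res))
}

#' Site-level mean heterozygosity over polymorphic loci
#'
#' @param het output of [heterozygosity()]
#' @return data frame with one row per site: number of polymorphic loci and
#'   mean `H_o`/`H_e` over them
#' @export
heterozygosity_site_means <- function(het) {
  keep <- het[!is.na(het$polymorphic) & het$polymorphic, , drop = FALSE]
  agg <- split(keep, keep$site)
  do.call(rbind, lapply(names(agg), function(s) {
    d <- agg[[s]]
    data.frame(site = s, n_polymorphic_loci = nrow(d),
               mean_H_o = mean(d$H_o), mean_H_e = mean(d$H_e))
  }))
}

# log conditional probability of a genotype array given its allele counts
# (the exact-test statistic): log[ n! 2^h prod(c_a!) / (prod(n_gg!) (2n)!) ]
log_genotype_array_prob <- function(g) {
  n <- nrow(g)
  h <- sum(g[, 1] != g[, 2])
  geno <- paste(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]))
  ngg <- as.numeric(table(geno))
  ca <- as.numeric(table(c(g[, 1], g[, 2])))
  lgamma(n + 1) - sum(lgamma(ngg + 1)) + h * log(2) +
    sum(lgamma(ca + 1)) - lgamma(2 * n + 1)
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' The statistic is the conditional probability of the observed genotype
#' array given its allele counts; the null is generated by random re-pairing
#' of the observed allele pool, and `p = (1 + b)/(1 + n_perm)` counts
#' replicates with probability less than or equal to the observed one.  A
#' one-sided homozygote-excess p-value (heterozygote count as or lower than
#' observed) is reported alongside, since breeding-site data are typically
#' screened for excess homozygosity.
#'
#' @param ds a [genotype_dataset()]
#' @param site,locus the cell to test
#' @param n_perm number of Monte-Carlo replicates
#' @param seed integer seed
#' @return a [perm_test_result()] with fields `p_homozygote_excess`, `n`,
#'   `n_alleles`; statistic and p are `NA` when the cell is monomorphic or
#'   `n < 3`
#' @export
hwe_test <- function(ds, site, locus, n_perm = 999, seed = 1L) {
  g <- site_locus_alleles(ds, site, locus)
  n <- nrow(g)
  n_alleles <- length(unique(c(g[, 1], g[, 2])))
  if (n < 3 || n_alleles < 2) {
    return(perm_test_result(NA_real_, NA_real_, n_perm, seed, "hwe_exact_mc",
                            list(p_homozygote_excess = NA_real_, n = n,
                                 n_alleles = n_alleles,
                                 site = site, locus = locus)))
  }
  obs_lp <- log_genotype_array_prob(g)
  obs_het <- sum(g[, 1] != g[, 2])
  pool <- c(g[, 1], g[, 2])
  b <- 0L; b_hom <- 0L
  withr::with_seed(sub_seed(seed, "hwe", site, locus), {
    for (r in seq_len(n_perm)) {
      perm <- sample(pool)
      gp <- cbind(perm[seq(1, 2 * n - 1, by = 2)], perm[seq(2, 2 * n, by = 2)])
      if (log_genotype_array_prob(gp) <= obs_lp + 1e-9) b <- b + 1L
      if (sum(gp[, 1] != gp[, 2]) <= obs_het) b_hom <- b_hom + 1L
    }
  })
  perm_test_result(obs_lp, perm_pvalue(b, n_perm), n_perm, seed, "hwe_exact_mc",
                   list(p_homozygote_excess = perm_pvalue(b_hom, n_perm),
                        n = n, n_alleles = n_alleles,
                        H_o = obs_het / n, site = site, locus = locus))
}

# genotypic log-likelihood-ratio G for independence of a two-way table
g_statistic <- function(x, y) {
  tab <- table(x, y)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  o <- as.numeric(tab)
  e <- as.numeric(e)
  2 * sum(ifelse(o > 0, o * log(o / e), 0))
}

#' Permutation test of linkage disequilibrium between two loci within a site
#'
#' The statistic is the genotypic log-likelihood-ratio `G` for independence
#' of the two-locus genotype contingency table; the null is generated by
#' permuting one locus's genotypes among individuals.
#'
#' @param ds a [genotype_dataset()]
#' @param site site label
#' @param locus_pair character vector of two locus names
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return a [perm_test_result()]; `NA` when either locus is monomorphic in
#'   the site or fewer than 3 individuals are genotyped at both loci
#' @export
ld_test <- function(ds, site, locus_pair, n_perm = 999, seed = 1L) {
  k <- which(ds$sites == site)
  l1 <- match(locus_pair[1], ds$loci)
  l2 <- match(locus_pair[2], ds$loci)
  g1 <- ds$calls[k, l1, , drop = FALSE]
  g2 <- ds$calls[k, l2, , drop = FALSE]
  ok <- !is.na(g1[, 1, 1]) & !is.na(g2[, 1, 1])
  geno <- function(g) paste(pmin(g[ok, 1, 1], g[ok, 1, 2]),
                            pmax(g[ok, 1, 1], g[ok, 1, 2]))
  x <- geno(g1); y <- geno(g2)
  poly <- function(g) length(unique(c(g[ok, 1, 1], g[ok, 1, 2]))) >= 2
  if (sum(ok) < 3 || !poly(g1) || !poly(g2)) {
    return(perm_test_result(NA_real_, NA_real_, n_perm, seed, "ld_g_perm",
                            list(site = site, locus_pair = locus_pair)))
  }
  obs <- g_statistic(x, y)
  b <- 0L
  withr::with_seed(sub_seed(seed, "ld", site, paste(locus_pair, collapse = ":")), {
    for (r in seq_len(n_perm)) {
      if (g_statistic(x, sample(y)) >= obs - 1e-9) b <- b + 1L
    }
  })
  perm_test_result(obs, perm_pvalue(b, n_perm), n_perm, seed, "ld_g_perm",
                   list(site = site, locus_pair = locus_pair, n = sum(ok)))
}

#' Bonferroni-adjusted significance level
#'
#' `family_alpha / n_tests`, optionally rounded to `sig_figs` significant
#' figures for reporting (the unrounded value is attached as attribute
#' `"unrounded"` and should be used for decisions).
#'
#' @param family_alpha family-wise level
#' @param n_tests number of tests in the family
#' @param sig_figs significant figures for the reported value; `NULL` for
#'   no rounding
#' @return adjusted level (rounded when `sig_figs` is given)
#' @export
bonferroni_alpha <- function(family_alpha, n_tests, sig_figs = NULL) {
  stopifnot(n_tests >= 1, family_alpha > 0)
  a <- family_alpha / n_tests
  out <- if (is.null(sig_figs)) a else signif(a, sig_figs)
  attr(out, "unrounded") <- a
  out
}

# distinct alleles per locus among a set of individuals (missing dropped);
# loci with no called genotype in the subsample are excluded from the mean
mean_richness <- function(calls, idx) {
  counts <- apply(calls[idx, , , drop = FALSE], 2, function(g) {
    a <- c(g[, 1], g[, 2])
    a <- a[!is.na(a)]
    if (!length(a)) NA_real_ else length(unique(a))
  })
  mean(counts, na.rm = TRUE)
}

#' Rarefied allelic richness curves
#'
#' For each unit (site, or region when `pooling = "region"` uses the group
#' label) and each standardized size `N`, repeatedly draws `N` individuals
#' without replacement, counts distinct alleles per locus in the subsample,
#' and averages over loci; the mean and SD over replicates are reported.
#' `N` equal to the unit's sample size is computed exactly (SD 0).  Sizes
#' exceeding a unit's sample size are skipped with a warning.
#'
#' @param ds a [genotype_dataset()]
#' @param N_values standardized sample sizes
#' @param n_reps subsampling replicates
#' @param seed integer seed
#' @param pooling `"site"` or `"region"` (pools member sites via the group
#'   label before subsampling)
#' @return data frame of class `rarefaction_curve`: `unit, n_unit, N,
#'   mean_richness, sd_richness, n_reps`
#' @export
rarefied_allelic_richness <- function(ds, N_values, n_reps = 1000, seed = 1L,
                                      pooling = c("site", "region")) {
  pooling <- match.arg(pooling)
  labels <- if (pooling == "site") ds$sites else ds$groups
  units <- unique(labels)
  rows <- list()
  for (u in units) {
    idx_u <- which(labels == u)
    for (N in sort(unique(as.integer(N_values)))) {
      if (N > length(idx_u)) {
        warning(sprintf("unit %s: N = %d exceeds sample size %d, skipped",
                        u, N, length(idx_u)))
        next
      }
      if (N == length(idx_u)) {
        m <- mean_richness(ds$calls, idx_u)
        rows[[length(rows) + 1]] <- data.frame(
          unit = u, n_unit = length(idx_u), N = N, mean_richness = m,
          sd_richness = 0, n_reps = 1L)
        next
      }
      reps <- withr::with_seed(sub_seed(seed, "rar", u, N), {
        vapply(seq_len(n_reps), function(r) {
          mean_richness(ds$calls, sample(idx_u, N))
        }, numeric(1))
      })
      rows[[length(rows) + 1]] <- data.frame(
        unit = u, n_unit = length(idx_u), N = N, mean_richness = mean(reps),
        sd_richness = stats::sd(reps), n_reps = n_reps)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(unit = character(), n_unit = integer(), N = integer(),
               mean_richness = numeric(), sd_richness = numeric(),
               n_reps = integer())
  }
  class(out) <- c("rarefaction_curve", class(out))
  out
}

#' Permutation test for a difference in rarefied allelic richness
#'
#' Pools the two units' individuals, re-splits at the observed sizes, and
#' recomputes the standardized richness difference at size `N`; the
#' two-sided p-value counts permuted `|difference|` at least as large as
#' observed, with the `(1 + b)/(1 + n_perm)` rule.  Both the observed and
#' permuted differences estimate richness with `n_reps` subsampling
#' replicates.
#'
#' @param ds a [genotype_dataset()]
#' @param units character vector of two unit labels
#' @param N standardized sample size (must not exceed either unit's size)
#' @param n_reps subsampling replicates per richness estimate
#' @param n_perm number of permutations
#' @param seed integer seed
#' @param pooling `"site"` or `"region"`
#' @return a [perm_test_result()] with the observed difference
#'   (`unit[1] - unit[2]`) as statistic
#' @export
richness_difference_test <- function(ds, units, N, n_reps = 100, n_perm = 199,
                                     seed = 1L, pooling = c("site", "region")) {
  pooling <- match.arg(pooling)
  labels <- if (pooling == "site") ds$sites else ds$groups
  ia <- which(labels == units[1]); ib <- which(labels == units[2])
  if (N > length(ia) || N > length(ib)) stop("N exceeds a unit's sample size")
  est <- function(idx, s) {
    if (N == length(idx)) return(mean_richness(ds$calls, idx))
    withr::with_seed(s, mean(vapply(seq_len(n_reps), function(r) {
      mean_richness(ds$calls, sample(idx, N))
    }, numeric(1))))
  }
  obs <- est(ia, sub_seed(seed, "rdt-a")) - est(ib, sub_seed(seed, "rdt-b"))
  pool <- c(ia, ib)
  b <- 0L
  withr::with_seed(sub_seed(seed, "rdt-perm"), {
    for (r in seq_len(n_perm)) {
      pa <- sample(pool, length(ia))
      pb <- setdiff(pool, pa)
      s <- sample.int(2^30, 2)
      d <- est(pa, s[1]) - est(pb, s[2])
      if (abs(d) >= abs(obs) - 1e-12) b <- b + 1L
    }
  })
  perm_test_result(obs, perm_pvalue(b, n_perm), n_perm, seed,
                   "richness_difference_perm",
                   list(units = units, N = N, n_reps = n_reps))
}

#' Haplotype identification and per-site frequencies
#'
#' Haplotypes are keyed by exact sequence identity after excluding, listwise
#' across the alignment, every position where any sequence carries `N` or a
#' gap.  Haplotype ids `H01, H02, ...` are assigned in order of decreasing
#' overall count (ties by first appearance).
#'
#' @param aln a [seq_alignment()]
#' @return list with `haplotypes` (data frame: id, key sequence, total
#'   count), `counts` (site x haplotype matrix) and `frequencies`
#'   (row-normalized counts)
#' @export
haplotype_frequencies <- function(aln) {
  if (!length(aln$ids)) stop("empty alignment")
  chars <- do.call(rbind, strsplit(aln$sequences, ""))
  keep <- apply(chars, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  key <- apply(chars[, keep, drop = FALSE], 1, paste, collapse = "")
  tot <- table(key)
  ord <- order(-as.numeric(tot), match(names(tot), key))
  hap_key <- names(tot)[ord]
  hap_id <- sprintf("H%02d", seq_along(hap_key))
  counts <- table(factor(aln$sites, levels = unique(aln$sites)),
                  factor(key, levels = hap_key))
  dimnames(counts)[[2]] <- hap_id
  counts <- unclass(counts)
  list(haplotypes = data.frame(id = hap_id, sequence = hap_key,
                               count = as.numeric(tot)[ord]),
       counts = counts,
       frequencies = counts / pmax(1, rowSums(counts)))
}

#' Screen for duplicate genotypes (putative resampled individuals)
#'
#' Flags every pair of individuals whose genotypes differ at no more than
#' `max_mismatch` alleles across all mutually non-missing loci (per locus:
#' `2 - |multiset intersection|`).  The default one-mismatch rule flags
#' pairs differing by zero or one allele.  Pairs with no comparable loci are
#' not flagged.
#'
#' @param ds a [genotype_dataset()]
#' @param max_mismatch maximum allele differences to flag
#' @return data frame `id_a, id_b, mismatches, n_loci_compared`
#' @export
find_duplicate_genotypes <- function(ds, max_mismatch = 1L) {
  n <- length(ds$ids)
  rows <- list()
  for (i in seq_len(max(0, n - 1))) {
    gi <- matrix(ds$calls[i, , ], ncol = 2)
    for (j in (i + 1):n) {
      gj <- matrix(ds$calls[j, , ], ncol = 2)
      ok <- !is.na(gi[, 1]) & !is.na(gj[, 1])
      if (!any(ok)) next
      mm <- 0L
      for (l in which(ok)) {
        mm <- mm + (2L - pair_overlap(gi[l, ], gj[l, ]))
        if (mm > max_mismatch) break
      }
      if (mm <= max_mismatch) {
        rows[[length(rows) + 1]] <- data.frame(
          id_a = ds$ids[i], id_b = ds$ids[j],
          mismatches = mm, n_loci_compared = sum(ok))
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(id_a = character(), id_b = character(),
                      mismatches = integer(), n_loci_compared = integer()))
  }
  do.call(rbind, rows)
}

#' Drop flagged duplicate genotypes
#'
#' Resolves each connected component of the duplicate graph to a single
#' retained individual: the first by input order (default) or the one with
#' fewest missing loci.
#'
#' @param ds a [genotype_dataset()]
#' @param max_mismatch passed to [find_duplicate_genotypes()]
#' @param keep `"first"` or `"least_missing"`
#' @return list with the reduced dataset (`dataset`), the flagged pair table
#'   (`flagged`) and the removed ids (`removed`)
#' @export
remove_duplicate_genotypes <- function(ds, max_mismatch = 1L,
                                       keep = c("first", "least_missing")) {
  keep <- match.arg(keep)
  fl <- find_duplicate_genotypes(ds, max_mismatch)
  if (!nrow(fl)) return(list(dataset = ds, flagged = fl, removed = character()))
  # union-find over flagged pairs
  parent <- stats::setNames(ds$ids, ds$ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (r in seq_len(nrow(fl))) {
    ra <- find(fl$id_a[r]); rb <- find(fl$id_b[r])
    if (ra != rb) parent[[rb]] <- ra
  }
  comp <- vapply(ds$ids, find, character(1))
  removed <- character()
  for (cc in unique(comp[duplicated(comp) | comp %in% comp[duplicated(comp)]])) {
    members <- which(comp == cc)
    if (length(members) < 2) next
    chosen <- if (keep == "first") members[1] else {
      members[which.min(rowSums(is.na(ds$calls[members, , 1, drop = FALSE])))]
    }
    removed <- c(removed, ds$ids[setdiff(members, chosen)])
  }
  list(dataset = subset_individuals(ds, !(ds$ids %in% removed)),
       flagged = fl, removed = removed)
}
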