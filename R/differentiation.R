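# Weir-Cockerham variance components for one locus.
# `alleles`: n x 2 matrix (missing rows dropped), `pop`: per-row labels.
# Returns c(a, b, c) summed over alleles, or NULL when undefined.
wc_components_locus <- function(alleles, pop) {
  ok <- !is.na(alleles[, 1])
  alleles <- alleles[ok, , drop = FALSE]
  pop <- pop[ok]
  pops <- unique(pop)
  r <- length(pops)
  if (r < 2) return(NULL)
  n_i <- as.numeric(table(factor(pop, levels = pops)))
  nbar <- mean(n_i)
  if (nbar <= 1) return(NULL)
  n_c <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  if (n_c <= 0) return(NULL)
  allele_set <- sort(unique(as.vector(alleles)))
  if (length(allele_set) < 2) return(c(a = 0, b = 0, c = 0))
  acc <- c(a = 0, b = 0, c = 0)
  het <- alleles[, 1] != alleles[, 2]
  for (al in allele_set) {
    cnt <- (alleles[, 1] == al) + (alleles[, 2] == al)
    p_i <- vapply(pops, function(s) sum(cnt[pop == s]) / (2 * sum(pop == s)),
                  numeric(1))
    h_i <- vapply(pops, function(s) mean(het[pop == s] & cnt[pop == s] == 1),
                  numeric(1))
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / n_c) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    acc <- acc + c(a = a, b = b, c = cc)
  }
  acc
}

#' Weir-Cockerham multi-locus fixation index (theta)
#'
#' Estimates F_ST from the 1984 variance components `a` (among
#' populations), `b` (among individuals within populations) and `c` (within
#' individuals), combined over alleles and loci as a ratio of sums
#' `theta = sum(a) / sum(a + b + c)`.  Missing genotypes are dropped per
#' locus (pairwise deletion).  Negative estimates are reported as computed.
#'
#' @param ds a [genotype_dataset()]
#' @param sites optional subset of site labels (default: all sites)
#' @return list with `theta`, the per-locus component table, and the number
#'   of usable loci; `theta` is `NA` with a diagnostic attribute when no
#'   shared polymorphic locus exists
#' @export
weir_cockerham_fst <- function(ds, sites = NULL) {
  if (is.null(sites)) sites <- unique(ds$sites)
  if (length(sites) < 2) stop("need at least two sites")
  keep <- ds$sites %in% sites
  pop <- ds$sites[keep]
  per_locus <- lapply(seq_along(ds$loci), function(l) {
    wc_components_locus(ds$calls[keep, l, , drop = TRUE], pop)
  })
  usable <- !vapply(per_locus, is.null, logical(1))
  comp <- do.call(rbind, per_locus[usable])
  if (is.null(comp) || sum(comp[, "a"] + comp[, "b"] + comp[, "c"]) == 0) {
    theta <- NA_real_
    attr(theta, "diagnostic") <- "no shared polymorphic locus among the sites"
    return(list(theta = theta, components = comp, n_loci_used = sum(usable)))
  }
  tab <- data.frame(locus = ds$loci[usable], comp)
  list(theta = sum(comp[, "a"]) / sum(comp[, "a"] + comp[, "b"] + comp[, "c"]),
       components = tab, n_loci_used = sum(usable))
}

#' Permutation test for pairwise F_ST
#'
#' Permutes individuals between the two sites at observed sizes and counts
#' permuted theta at least as large as observed (one-sided: differentiation
#' inflates theta), with `p = (1 + b)/(1 + n_perm)`.
#'
#' @param ds a [genotype_dataset()]
#' @param site_pair character vector of two site labels
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return a [perm_test_result()] with theta as statistic
#' @export
fst_permutation_test <- function(ds, site_pair, n_perm = 999, seed = 1L) {
  stopifnot(length(site_pair) == 2)
  sub <- subset_individuals(ds, ds$sites %in% site_pair)
  obs <- weir_cockerham_fst(sub, site_pair)$theta
  if (is.na(obs)) {
    return(perm_test_result(NA_real_, NA_real_, n_perm, seed, "fst_perm",
                            list(site_pair = site_pair)))
  }
  labs <- sub$sites
  theta_for <- function(pop) {
    per_locus <- lapply(seq_along(sub$loci), function(l) {
      wc_components_locus(sub$calls[, l, , drop = TRUE], pop)
    })
    comp <- do.call(rbind, per_locus[!vapply(per_locus, is.null, logical(1))])
    if (is.null(comp)) return(NA_real_)
    tot <- sum(comp[, "a"] + comp[, "b"] + comp[, "c"])
    if (tot == 0) NA_real_ else sum(comp[, "a"]) / tot
  }
  b <- 0L
  withr::with_seed(sub_seed(seed, "fst", paste(site_pair, collapse = ":")), {
    for (r in seq_len(n_perm)) {
      tp <- theta_for(sample(labs))
      if (!is.na(tp) && tp >= obs - 1e-12) b <- b + 1L
    }
  })
  perm_test_result(obs, perm_pvalue(b, n_perm), n_perm, seed, "fst_perm",
                   list(site_pair = site_pair,
                        n = as.list(table(labs))))
}

# SSD decomposition of squared distances for a labeling
amova_ss <- function(sq, labels) {
  N <- nrow(sq)
  ss_total <- sum(sq) / (2 * N)
  ss_within <- 0
  for (s in unique(labels)) {
    idx <- which(labels == s)
    ss_within <- ss_within + sum(sq[idx, idx]) / (2 * length(idx))
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

#' One-level AMOVA on a distance matrix
#'
#' Excoffier-Smouse-Quattro analysis of molecular variance: squared pairwise
#' distances are decomposed into among-site and within-site sums of squares;
#' `sigma2_within = SS_within / (N - k)` and
#' `sigma2_among = (MS_among - sigma2_within) / n0` with `n0` the standard
#' unequal-sample-size coefficient.  Significance is assessed by permuting
#' individuals among sites at fixed sizes and counting permuted Phi_ST at
#' least as large as observed.  Sites with a single member are excluded with
#' a warning.
#'
#' @param dm a [dist_matrix()]
#' @param labels per-individual site label, aligned with `dm$ids`
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return object of class `amova_result`: data frame `table` (df, SS,
#'   sigma2, percent), `phi_st`, `p`, `n_perm`, `seed`, `marker`,
#'   `degenerate` flag, `excluded` ids
#' @export
amova <- function(dm, labels, n_perm = 16000, seed = 1L) {
  stopifnot(length(labels) == length(dm$ids))
  labels <- as.character(labels)
  sizes <- table(labels)
  excluded <- character()
  if (any(sizes < 2)) {
    drop_sites <- names(sizes)[sizes < 2]
    warning(sprintf("excluding singleton site(s): %s (within-site d.f. would be 0)",
                    paste(drop_sites, collapse = ", ")))
    keep <- !(labels %in% drop_sites)
    excluded <- dm$ids[!keep]
    dm <- dist_matrix(dm$values[keep, keep], dm$ids[keep], dm$metric,
                      dm$parameters)
    labels <- labels[keep]
    sizes <- table(labels)
  }
  k <- length(sizes)
  N <- length(labels)
  if (k < 2) stop("need at least two sites with >= 2 members")
  sq <- dm$values^2
  ss <- amova_ss(sq, labels)
  df_among <- k - 1
  df_within <- N - k
  n0 <- (N - sum(sizes^2) / N) / df_among
  sigma_within <- ss["within"] / df_within
  sigma_among <- (ss["among"] / df_among - sigma_within) / n0
  total <- sigma_among + sigma_within
  degenerate <- total <= 0
  phi <- if (degenerate) NA_real_ else unname(sigma_among / total)
  pct <- if (degenerate) c(among = 0, within = 100) else {
    c(among = 100 * sigma_among / total, within = 100 * sigma_within / total)
  }

  p <- NA_real_
  if (!degenerate && n_perm >= 1) {
    b <- 0L
    withr::with_seed(sub_seed(seed, "amova", dm$metric), {
      for (r in seq_len(n_perm)) {
        ssp <- amova_ss(sq, sample(labels))
        sw <- ssp["within"] / df_within
        sa <- (ssp["among"] / df_among - sw) / n0
        phi_p <- sa / (sa + sw)
        if (!is.na(phi_p) && phi_p >= phi - 1e-12) b <- b + 1L
      }
    })
    p <- perm_pvalue(b, n_perm)
  } else if (degenerate) {
    p <- 1
  }
  structure(list(
    table = data.frame(
      component = c("among_sites", "within_sites"),
      df = c(df_among, df_within),
      SS = unname(ss[c("among", "within")]),
      sigma2 = c(unname(sigma_among), unname(sigma_within)),
      percent = unname(pct)),
    phi_st = phi, p = p, n_perm = n_perm, seed = seed,
    marker = dm$metric, degenerate = degenerate, excluded = excluded),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA (%s): Phi_ST = %s, p = %s (%d permutations)\n",
              x$marker,
              ifelse(is.na(x$phi_st), "NA", sprintf("%.4f", x$phi_st)),
              ifelse(is.na(x$p), "NA", format(x$p, digits = 4)), x$n_perm))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Average pairwise differences within and between sites
#'
#' `within[i]` is the mean distance over unordered pairs inside site `i`
#' (`NA` for singleton sites); `between[i, j]` is the mean over all cross
#' pairs (uncorrected).
#'
#' @param dm a [dist_matrix()]
#' @param labels per-individual site label
#' @return list with `within` (named vector) and `between` (symmetric
#'   matrix with `NA` diagonal)
#' @export
avg_pairwise_differences <- function(dm, labels) {
  labels <- as.character(labels)
  sites <- unique(labels)
  V <- dm$values
  within <- stats::setNames(vapply(sites, function(s) {
    idx <- which(labels == s)
    if (length(idx) < 2) return(NA_real_)
    sum(V[idx, idx]) / (length(idx) * (length(idx) - 1))
  }, numeric(1)), sites)
  between <- matrix(NA_real_, length(sites), length(sites),
                    dimnames = list(sites, sites))
  for (i in seq_along(sites)) {
    for (j in seq_along(sites)) {
      if (i == j) next
      ii <- which(labels == sites[i]); jj <- which(labels == sites[j])
      between[i, j] <- mean(V[ii, jj, drop = FALSE])
    }
  }
  list(within = within, between = between)
}
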