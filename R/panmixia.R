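# mean within-group distances and the pooled mean for a two-site labeling
kst_parts <- function(V, idx1, idx2, weights = c("size", "hbk")) {
  weights <- match.arg(weights)
  n1 <- length(idx1); n2 <- length(idx2); n <- n1 + n2
  K1 <- sum(V[idx1, idx1]) / (n1 * (n1 - 1))
  K2 <- sum(V[idx2, idx2]) / (n2 * (n2 - 1))
  w <- if (weights == "size") c(n1, n2) / n else c(n1 - 1, n2 - 1) / (n - 2)
  KS <- w[1] * K1 + w[2] * K2
  KT <- sum(V) / (n * (n - 1))
  list(K1 = K1, K2 = K2, K_S = KS, K_T = KT,
       K_ST = if (KT > 0) 1 - KS / KT else NA_real_)
}

#' Hudson-Boos-Kaplan K_ST statistic for two sites
#'
#' `K_i` is the mean pairwise distance within site `i`; `K_S` is the
#' sample-size-weighted average of the `K_i`; `K_T` is the mean pairwise
#' distance over all individuals pooled; `K_ST = 1 - K_S/K_T` measures the
#' deficit of within-site relative to total diversity.  With
#' `weights = "hbk"` the `(n_i - 1)`-proportional weighting used in parts of
#' the subdivision-test literature is applied instead of the plain
#' sample-size weights.
#'
#' @param dm a [dist_matrix()]
#' @param labels per-individual labels taking exactly two values, each with
#'   >= 2 members
#' @param weights `"size"` (default) or `"hbk"`
#' @return object of class `kst_result` (no p-value); when `K_T = 0` the
#'   statistic is `NA` with `degenerate = TRUE` (panmixia trivially
#'   non-rejectable)
#' @export
kst_statistic <- function(dm, labels, weights = c("size", "hbk")) {
  weights <- match.arg(weights)
  labels <- as.character(labels)
  stopifnot(length(labels) == length(dm$ids))
  lev <- unique(labels)
  if (length(lev) != 2) stop("labels must take exactly two values")
  idx1 <- which(labels == lev[1]); idx2 <- which(labels == lev[2])
  if (length(idx1) < 2 || length(idx2) < 2) {
    stop("each site needs >= 2 members for K_ST")
  }
  parts <- kst_parts(dm$values, idx1, idx2, weights)
  structure(c(list(site_pair = lev, n = c(length(idx1), length(idx2)),
                   degenerate = parts$K_T == 0,
                   metric = dm$metric, weights = weights,
                   p = NA_real_, n_perm = NA_integer_, seed = NA_integer_,
                   exact = FALSE),
              parts),
            class = "kst_result")
}

#' @export
print.kst_result <- function(x, ...) {
  cat(sprintf("K_ST %s vs %s (n = %d, %d; %s): K_S = %.5g, K_T = %.5g, K_ST = %s\n",
              x$site_pair[1], x$site_pair[2], x$n[1], x$n[2], x$metric,
              x$K_S, x$K_T,
              ifelse(is.na(x$K_ST), "NA (degenerate)", sprintf("%.5g", x$K_ST))))
  if (!is.na(x$p)) {
    cat(sprintf("  p = %s (%s, n_perm = %d)\n", format(x$p, digits = 4),
                if (x$exact) "exhaustive" else "Monte Carlo", x$n_perm))
  }
  invisible(x)
}

#' Permutation test of panmixia based on K_ST
#'
#' Permutes site labels over individuals at fixed sample sizes; the
#' one-sided p-value counts permuted `K_ST` at least as large as observed
#' (large `K_ST` indicates differentiation), with the
#' `(1 + b)/(1 + n_perm)` rule for Monte-Carlo sampling.  When the number
#' of distinct label arrangements `choose(n, n1)` is at most `exact_limit`,
#' all arrangements are enumerated and the p-value is the exact proportion
#' of arrangements with `K_ST >= observed` (the observed one included).
#'
#' @param dm a [dist_matrix()]
#' @param labels two-site labeling
#' @param n_perm Monte-Carlo permutations
#' @param seed integer seed
#' @param weights see [kst_statistic()]
#' @param exact_limit arrangement count at or below which enumeration is used
#' @return a `kst_result` with `p`, `n_perm` (or arrangement count), `exact`
#' @export
kst_permutation_test <- function(dm, labels, n_perm = 5000, seed = 1L,
                                 weights = c("size", "hbk"),
                                 exact_limit = 20000) {
  weights <- match.arg(weights)
  res <- kst_statistic(dm, labels, weights)
  if (res$degenerate) {
    res$p <- 1
    res$n_perm <- 0L
    return(res)
  }
  labels <- as.character(labels)
  lev <- res$site_pair
  n1 <- res$n[1]; n <- sum(res$n)
  V <- dm$values
  obs <- res$K_ST
  n_arr <- choose(n, n1)
  if (n_arr <= exact_limit) {
    combos <- utils::combn(n, n1)
    ge <- 0L
    for (c_i in seq_len(ncol(combos))) {
      idx1 <- combos[, c_i]
      k <- kst_parts(V, idx1, setdiff(seq_len(n), idx1), weights)$K_ST
      if (!is.na(k) && k >= obs - 1e-12) ge <- ge + 1L
    }
    res$p <- ge / n_arr
    res$n_perm <- as.integer(n_arr)
    res$exact <- TRUE
  } else {
    b <- 0L
    withr::with_seed(sub_seed(seed, "kst", paste(lev, collapse = ":")), {
      for (r in seq_len(n_perm)) {
        idx1 <- sample.int(n, n1)
        k <- kst_parts(V, idx1, setdiff(seq_len(n), idx1), weights)$K_ST
        if (!is.na(k) && k >= obs - 1e-12) b <- b + 1L
      }
    })
    res$p <- perm_pvalue(b, n_perm)
    res$n_perm <- as.integer(n_perm)
  }
  res$seed <- seed
  res
}

#' All-pairs panmixia screen and panmictic groupings
#'
#' Runs [kst_permutation_test()] for every pair of sites with at least two
#' members and builds the panmixia graph whose edges are pairs not rejected
#' at level `alpha`; the reported groups are its connected components.
#' Following the study design this implements, pairwise decisions use raw
#' p-values; a Bonferroni-adjusted call (level `alpha / n_pairs`) is
#' reported alongside for comparison.
#'
#' @param dm a [dist_matrix()]
#' @param labels per-individual site labels (any number of sites)
#' @param n_perm permutations per pair
#' @param seed integer seed (sub-seeded per pair)
#' @param alpha rejection level for the panmixia decision
#' @param weights see [kst_statistic()]
#' @return list: `table` (pair, n, K_ST, p, panmictic, panmictic_bonferroni),
#'   `groups` (list of character vectors), `skipped` (sites with < 2
#'   members), `alpha`, `marker`
#' @export
panmixia_screen <- function(dm, labels, n_perm = 5000, seed = 1L,
                            alpha = 0.05, weights = c("size", "hbk")) {
  weights <- match.arg(weights)
  labels <- as.character(labels)
  sizes <- table(labels)
  usable <- names(sizes)[sizes >= 2]
  skipped <- setdiff(names(sizes), usable)
  if (length(usable) < 2) stop("need >= 2 sites with >= 2 members")
  pairs <- utils::combn(usable, 2)
  rows <- list()
  for (c_i in seq_len(ncol(pairs))) {
    pr <- pairs[, c_i]
    keep <- labels %in% pr
    sub <- dist_matrix(dm$values[keep, keep], dm$ids[keep], dm$metric,
                       dm$parameters)
    r <- kst_permutation_test(sub, labels[keep], n_perm = n_perm,
                              seed = sub_seed(seed, "screen", pr[1], pr[2]),
                              weights = weights)
    rows[[c_i]] <- data.frame(site_a = pr[1], site_b = pr[2],
                              n_a = sum(labels == pr[1]),
                              n_b = sum(labels == pr[2]),
                              K_ST = r$K_ST, p = r$p,
                              exact = r$exact)
  }
  tab <- do.call(rbind, rows)
  n_pairs <- nrow(tab)
  tab$panmictic <- tab$p > alpha
  tab$panmictic_bonferroni <- tab$p > alpha / n_pairs
  # connected components of the panmixia graph (union-find)
  parent <- stats::setNames(usable, usable)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (r in which(tab$panmictic)) {
    ra <- find(tab$site_a[r]); rb <- find(tab$site_b[r])
    if (ra != rb) parent[[rb]] <- ra
  }
  comp <- vapply(usable, find, character(1))
  groups <- unname(split(usable, comp))
  list(table = tab, groups = groups, skipped = skipped, alpha = alpha,
       marker = dm$metric)
}

#' Write a panmixia decision table and edge list
#'
#' @param screen output of [panmixia_screen()]
#' @param path CSV path for the decision table; an edge list of the
#'   panmixia graph is written alongside with suffix `_edges.txt`
#' @return `path`, invisibly
#' @export
write_panmixia_csv <- function(screen, path) {
  utils::write.csv(cbind(screen$table, marker = screen$marker), path,
                   row.names = FALSE)
  edges <- screen$table[screen$table$panmictic, c("site_a", "site_b")]
  writeLines(sprintf("%s -- %s", edges$site_a, edges$site_b),
             sub("\\.csv$", "_edges.txt", path))
  invisible(path)
}
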