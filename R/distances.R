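#' Pairwise distance matrix with metric metadata
#'
#' @param values symmetric numeric matrix with zero diagonal
#' @param ids row/column identifiers
#' @param metric one of `"tn93_gamma"`, `"genotype_smouse_peakall"`,
#'   `"allele_count_diff"` (or another tag)
#' @param parameters named list of metric parameters (e.g. gamma shape
#'   `alpha`, nominal rate categories `K`)
#' @return object of class `dist_matrix`
#' @export
dist_matrix <- function(values, ids, metric, parameters = list()) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), nrow(values) == length(ids))
  if (any(abs(values - t(values)) > 1e-12, na.rm = TRUE)) {
    stop("distance matrix must be symmetric")
  }
  if (any(diag(values) != 0)) stop("distance matrix diagonal must be 0")
  if (any(values < 0, na.rm = TRUE)) stop("distances must be non-negative")
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = as.character(ids),
                 metric = metric, parameters = parameters),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s): %d x %d\n", x$metric, nrow(x$values),
              ncol(x$values)))
  invisible(x)
}

#' Write a distance matrix as square CSV with a metadata comment line
#' @param dm a [dist_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dist_csv <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  pars <- if (length(dm$parameters)) {
    paste(names(dm$parameters), unlist(dm$parameters), sep = "=", collapse = " ")
  } else ""
  writeLines(sprintf("# metric=%s %s", dm$metric, pars), con)
  utils::write.csv(as.data.frame(dm$values), con)
  invisible(path)
}

# split two sequences into comparable per-position vectors, pairwise-deleting
# positions where either carries N or a gap
comparable_positions <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  list(a = a[ok], b = b[ok])
}

#' Gamma-corrected Tamura-Nei (TN93) pairwise distance
#'
#' Computes the TN93 distance (substitutions/site) between two aligned
#' sequences with a continuous-gamma rate-variation correction of shape
#' `alpha`.  Base frequencies are estimated from the two sequences pooled
#' (the classic pairwise convention).  Transition proportions are counted
#' separately for purines (`P1`: A<->G) and pyrimidines (`P2`: C<->T),
#' transversions as `Q`; positions where either sequence carries `N` or a
#' gap are excluded pairwise.  With `alpha = Inf` the uncorrected TN93
#' distance is returned.  The discrete-category count sometimes quoted
#' alongside a gamma shape applies to likelihood phylogenetics, not this
#' pairwise closed form; it can be recorded as metadata on the matrix but
#' plays no role here.
#'
#' @param seq_a,seq_b equal-length aligned sequences
#' @param alpha gamma shape parameter, > 0 (or `Inf`)
#' @param cap_saturated if not `NULL`, return this value instead of raising
#'   when the distance saturates (a log/power argument falls to 0 or below)
#' @return distance in substitutions per site
#' @export
tn93_gamma_distance <- function(seq_a, seq_b, alpha, cap_saturated = NULL) {
  stopifnot(alpha > 0)
  cp <- comparable_positions(seq_a, seq_b)
  n <- length(cp$a)
  if (n == 0) stop("coverage error: no comparable sites between the pair")

  counts <- table(factor(c(cp$a, cp$b), levels = c("A", "C", "G", "T")))
  g <- as.numeric(counts) / (2 * n)
  names(g) <- c("A", "C", "G", "T")
  gR <- g["A"] + g["G"]; gY <- g["C"] + g["T"]

  diff <- cp$a != cp$b
  pur <- c("A", "G")
  P1 <- mean(diff & cp$a %in% pur & cp$b %in% pur)            # A<->G
  P2 <- mean(diff & cp$a %in% c("C", "T") & cp$b %in% c("C", "T"))
  Q  <- mean(diff) - P1 - P2                                  # transversions

  if (P1 + P2 + Q == 0) return(0)
  k1 <- if (gR > 0) 2 * g[["A"]] * g[["G"]] / gR else 0
  k2 <- if (gY > 0) 2 * g[["T"]] * g[["C"]] / gY else 0
  k3 <- 2 * gR * gY - k1 * gY - k2 * gR

  # a zero-weight class with observed changes of that class cannot be
  # corrected; a zero-weight class with no such changes contributes 0
  saturate <- function() {
    if (!is.null(cap_saturated)) return(cap_saturated)
    stop("saturation error: TN93 distance undefined for this pair")
  }
  term <- function(k, P, denom) {
    if (k == 0) {
      if (P > 0) return(NA_real_)
      return(0)
    }
    w <- 1 - P / k - if (denom > 0) Q / (2 * denom) else 0
    if (w <= 0) return(NA_real_)
    if (is.finite(alpha)) alpha * k * (w^(-1 / alpha) - 1) else -k * log(w)
  }
  t1 <- term(k1, P1, gR)
  t2 <- term(k2, P2, gY)
  t3 <- if (k3 == 0) {
    if (Q > 0) NA_real_ else 0
  } else {
    w3 <- 1 - Q / (2 * gR * gY)
    if (w3 <= 0) NA_real_
    else if (is.finite(alpha)) alpha * k3 * (w3^(-1 / alpha) - 1)
    else -k3 * log(w3)
  }
  if (anyNA(c(t1, t2, t3))) return(saturate())
  unname(max(0, t1 + t2 + t3))
}

#' All-pairs TN93+gamma distances for an alignment
#'
#' @param aln a [seq_alignment()]
#' @param alpha gamma shape parameter
#' @param K nominal discrete rate categories recorded as metadata
#' @param cap_saturated see [tn93_gamma_distance()]
#' @return a [dist_matrix()] with metric tag `"tn93_gamma"`
#' @export
pairwise_sequence_distances <- function(aln, alpha, K = 4L, cap_saturated = NULL) {
  n <- length(aln$ids)
  if (n < 2) stop("need at least two sequences")
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- tryCatch(
        tn93_gamma_distance(aln$sequences[i], aln$sequences[j], alpha,
                            cap_saturated = cap_saturated),
        error = function(e) {
          stop(sprintf("pair (%s, %s): %s", aln$ids[i], aln$ids[j],
                       conditionMessage(e)), call. = FALSE)
        })
      m[i, j] <- m[j, i] <- d
    }
  }
  dist_matrix(m, aln$ids, "tn93_gamma", list(alpha = alpha, K = K))
}

# single-locus multiset distance scheme on two allele pairs:
# 0 for (ii,ii)/(ij,ij); 1 for (ii,ij)/(ij,ik); 2 for (ij,kl);
# 3 for (ii,jk); 4 for (ii,jj)
single_locus_distance <- function(a, b) {
  homA <- a[1] == a[2]
  homB <- b[1] == b[2]
  ov <- pair_overlap(a, b)
  if (ov == 2L) return(0L)
  if (homA && homB) return(4L)                 # (ii, jj)
  if (homA != homB) return(if (ov == 1L) 1L else 3L)  # (ii,ij) / (ii,jk)
  if (ov == 1L) 1L else 2L                     # (ij,ik) / (ij,kl)
}

#' Summed single-locus genotype distance between two individuals
#'
#' Applies the 0-4 single-locus scheme (alleles compared as unordered
#' multisets) at every locus where both genotypes are called, and sums.
#'
#' @param g_a,g_b `n_loci x 2` integer matrices of allele pairs (`NA` rows
#'   mark missing genotypes)
#' @return non-negative integer distance
#' @export
genotype_distance <- function(g_a, g_b) {
  g_a <- matrix(as.integer(g_a), ncol = 2)
  g_b <- matrix(as.integer(g_b), ncol = 2)
  stopifnot(nrow(g_a) == nrow(g_b))
  ok <- !is.na(g_a[, 1]) & !is.na(g_b[, 1])
  if (!any(ok)) stop("coverage error: no comparable loci between the pair")
  s <- 0L
  for (l in which(ok)) s <- s + single_locus_distance(g_a[l, ], g_b[l, ])
  s
}

#' Allele-count-difference distance between two individuals
#'
#' Per locus, `2 - |multiset intersection of the two allele pairs|`, summed
#' over loci where both genotypes are called -- the "number of different
#' alleles" distance used for microsatellite AMOVA.
#'
#' @inheritParams genotype_distance
#' @return non-negative integer distance
#' @export
allele_count_diff_distance <- function(g_a, g_b) {
  g_a <- matrix(as.integer(g_a), ncol = 2)
  g_b <- matrix(as.integer(g_b), ncol = 2)
  stopifnot(nrow(g_a) == nrow(g_b))
  ok <- !is.na(g_a[, 1]) & !is.na(g_b[, 1])
  if (!any(ok)) stop("coverage error: no comparable loci between the pair")
  s <- 0L
  for (l in which(ok)) s <- s + (2L - pair_overlap(g_a[l, ], g_b[l, ]))
  s
}

#' All-pairs genotype distance matrix
#'
#' @param ds a [genotype_dataset()]
#' @param metric `"genotype_smouse_peakall"` (the summed 0-4 scheme) or
#'   `"allele_count_diff"`
#' @return a [dist_matrix()]
#' @export
pairwise_genotype_distances <- function(ds,
                                        metric = c("genotype_smouse_peakall",
                                                   "allele_count_diff")) {
  metric <- match.arg(metric)
  fn <- if (metric == "genotype_smouse_peakall") genotype_distance
        else allele_count_diff_distance
  n <- length(ds$ids)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    gi <- ds$calls[i, , , drop = TRUE]
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- fn(gi, ds$calls[j, , , drop = TRUE])
    }
  }
  dist_matrix(m, ds$ids, metric)
}
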