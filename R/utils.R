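#' Permutation test p-value
#'
#' Applies the add-one rule `p = (1 + b) / (1 + n_perm)`, where `b` counts
#' null replicates at least as extreme as the observed statistic.  The rule
#' guarantees `p >= 1/(1 + n_perm)` and is the convention used by all
#' permutation tests in this package.
#'
#' @param n_extreme number of null replicates as or more extreme than observed
#' @param n_perm number of permutations drawn
#' @return p-value in `(0, 1]`
#' @export
perm_pvalue <- function(n_extreme, n_perm) {
  stopifnot(n_perm >= 1, n_extreme >= 0, n_extreme <= n_perm)
  (1 + n_extreme) / (1 + n_perm)
}

#' Container for a permutation test result
#'
#' Shared by the K_ST, F_ST, AMOVA, Hardy-Weinberg, linkage and seasonal
#' movement tests: the observed statistic, number of permutations, p-value
#' and the seed that fixed the null draws.
#'
#' @param statistic observed value of the test statistic
#' @param p p-value (may be `NA` when the test is undefined)
#' @param n_perm number of permutations (or exact arrangement count)
#' @param seed integer seed used for the null
#' @param method short label for the test
#' @param extra named list of additional fields attached to the result
#' @return object of class `perm_test`
#' @export
perm_test_result <- function(statistic, p, n_perm, seed, method, extra = list()) {
  out <- c(list(statistic = statistic, p = p, n_perm = n_perm,
                seed = seed, method = method), extra)
  class(out) <- "perm_test"
  out
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %s (n_perm = %d, seed = %s)\n",
              x$method, x$statistic,
              ifelse(is.na(x$p), "NA", format(x$p, digits = 4)),
              x$n_perm, format(x$seed)))
  invisible(x)
}

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' Every stochastic stage of the pipeline draws its seed from the master
#' seed and a label naming the stage (and site/locus/replicate where
#' relevant), so results are independent across streams yet fixed by one
#' global seed.  Implemented as a polynomial string hash modulo
#' `2^31 - 1`, so the value is always a valid 32-bit R seed.
#'
#' @param seed master integer seed
#' @param ... label components, concatenated with "/"
#' @return an integer seed
#' @export
sub_seed <- function(seed, ...) {
  label <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Parse ISO-8601-ish timestamps as UTC, element-wise: a midnight value
# printed date-only must not force date-only parsing onto the whole vector.
parse_utc_times <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  ts <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  retry <- is.na(ts)
  ts[retry] <- as.POSIXct(x[retry], tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  retry <- is.na(ts)
  ts[retry] <- as.POSIXct(x[retry], tz = "UTC", format = "%Y-%m-%d")
  ts
}

# size of the multiset intersection of two length-2 allele vectors
pair_overlap <- function(a, b) {
  s <- 0L
  rem <- b
  for (x in a) {
    j <- match(x, rem)
    if (!is.na(j)) {
      s <- s + 1L
      rem <- rem[-j]
    }
  }
  s
}
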