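# Small fixture builders shared across the suite.  Everything is generated
# in code; no data files.

# genotype dataset from a list of per-individual genotype matrices
make_ds <- function(genos, sites, loci = NULL, ids = NULL) {
  n <- length(genos)
  n_loci <- nrow(genos[[1]])
  if (is.null(loci)) loci <- sprintf("L%d", seq_len(n_loci))
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(n))
  calls <- array(NA_integer_, c(n, n_loci, 2))
  for (k in seq_len(n)) calls[k, , ] <- genos[[k]]
  genotype_dataset(ids, sites, loci, calls)
}

# single-locus genotype matrix shorthand: g(1,2) is a heterozygote 1/2
g1 <- function(a, b) matrix(c(a, b), ncol = 2)

# distance matrix from the upper triangle given row-wise
make_dm <- function(upper, n, ids = sprintf("i%d", seq_len(n)), metric = "toy") {
  V <- matrix(0, n, n)
  V[upper.tri(V)] <- upper
  V <- V + t(V)
  dist_matrix(V, ids, metric)
}

# worked 2+2 fixture: within-site distances 1, between-site distances 3
worked_kst_dm <- function() {
  V <- matrix(3, 4, 4)
  diag(V) <- 0
  V[1, 2] <- V[2, 1] <- 1
  V[3, 4] <- V[4, 3] <- 1
  dist_matrix(V, paste0("i", 1:4), "toy")
}

# dataset with two sites fixed for different alleles at every locus
fixed_difference_ds <- function(n_per_site = 4, n_loci = 2) {
  genos <- c(replicate(n_per_site, matrix(1L, n_loci, 2), simplify = FALSE),
             replicate(n_per_site, matrix(2L, n_loci, 2), simplify = FALSE))
  make_ds(genos, rep(c("A", "B"), each = n_per_site))
}

# hourly haulout series from a 24-vector of dry fractions repeated over days
make_haulout_series <- function(day_profile, days,
                                start = as.POSIXct("2006-05-01", tz = "UTC")) {
  ts <- start + 3600 * (seq_len(days * 24) - 1)
  data.frame(timestamp = ts, dry_fraction = rep(day_profile, days))
}

# a stationary track with evenly spaced hourly fixes
stationary_track <- function(n = 24, lat = 70, lon = -150, id = "st01") {
  telemetry_track(id, data.frame(
    timestamp = as.POSIXct("2006-01-01", tz = "UTC") + 3600 * seq_len(n),
    lat = lat, lon = lon))
}
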