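#' Island-model genotype simulation spec
#'
#' Describes a multi-site microsatellite sampling design in which each site
#' has drifted from a common ancestral allele pool.  Per-site drift is
#' parameterized directly by a target fixation index `F`: site allele
#' frequencies are drawn from a Dirichlet centred on the ancestral
#' frequencies with concentration `p * (1 - F) / F`, which gives
#' `E[(p_site - p)^2] = p (1 - p) F` -- the quantity the Weir-Cockerham
#' estimator targets.  Alternatively a scaled migration rate `Nm` may be
#' given and is converted via the island-model equilibrium `F = 1/(1 + 4Nm)`.
#'
#' @param n_sites number of sampling sites
#' @param n_per_site individuals per site (scalar or length-`n_sites`)
#' @param n_loci number of loci
#' @param n_alleles_per_locus alleles per locus (scalar or length-`n_loci`)
#' @param target_fst per-site drift level in `[0, 1)` (scalar or per-site);
#'   0 means the site carries the ancestral frequencies exactly
#' @param Nm scaled migration; used when `target_fst` is `NULL`
#' @param site_names optional site labels
#' @param missing_rate per-genotype missingness probability
#' @param seed integer seed fixing all randomness
#' @return object of class `island_model_spec`
#' @export
island_model_spec <- function(n_sites, n_per_site, n_loci, n_alleles_per_locus,
                              target_fst = NULL, Nm = NULL, site_names = NULL,
                              missing_rate = 0, seed = 1L) {
  if (is.null(target_fst)) {
    if (is.null(Nm)) stop("give either target_fst or Nm")
    if (any(Nm < 0)) stop("Nm must be >= 0")
    target_fst <- 1 / (1 + 4 * Nm)
  }
  if (any(target_fst < 0 | target_fst >= 1)) {
    stop("target_fst must lie in [0, 1)")
  }
  n_per_site <- rep_len(as.integer(n_per_site), n_sites)
  if (any(n_per_site < 2)) stop("n_per_site must be >= 2")
  structure(list(
    n_sites = as.integer(n_sites),
    n_per_site = n_per_site,
    n_loci = as.integer(n_loci),
    n_alleles_per_locus = rep_len(as.integer(n_alleles_per_locus), n_loci),
    target_fst = rep_len(as.numeric(target_fst), n_sites),
    site_names = if (is.null(site_names)) sprintf("site%02d", seq_len(n_sites))
                 else as.character(site_names),
    missing_rate = missing_rate,
    seed = as.integer(seed)),
    class = "island_model_spec")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (all(x == 0)) { # numerically degenerate concentration: pick one category
    x[sample.int(length(alpha), 1)] <- 1
  }
  x / sum(x)
}

#' Simulate multi-site genotypes under Dirichlet drift from a common pool
#'
#' Draws ancestral allele frequencies per locus, drifts each site's
#' frequencies around them at that site's target `F`, then samples diploid
#' genotypes in Hardy-Weinberg proportions within sites.  Deterministic
#' under the spec seed; sub-streams are derived per locus and site so
#' partial structures are reproducible.
#'
#' @param spec an [island_model_spec()]
#' @return a [genotype_dataset()]
#' @export
simulate_island_genotypes <- function(spec) {
  stopifnot(inherits(spec, "island_model_spec"))
  n_tot <- sum(spec$n_per_site)
  loci <- sprintf("L%02d", seq_len(spec$n_loci))
  sites <- rep(spec$site_names, spec$n_per_site)
  ids <- paste0(sites, "_", unlist(lapply(spec$n_per_site, seq_len)))
  calls <- array(NA_integer_, dim = c(n_tot, spec$n_loci, 2))
  for (l in seq_len(spec$n_loci)) {
    K <- spec$n_alleles_per_locus[l]
    anc <- withr::with_seed(sub_seed(spec$seed, "anc", l),
                            rdirichlet1(rep(2, K)))
    row0 <- 0L
    for (s in seq_len(spec$n_sites)) {
      Fst <- spec$target_fst[s]
      p <- if (Fst <= 0) anc else {
        withr::with_seed(sub_seed(spec$seed, "freq", l, s),
                         rdirichlet1(anc * (1 - Fst) / Fst))
      }
      n <- spec$n_per_site[s]
      g <- withr::with_seed(sub_seed(spec$seed, "geno", l, s), {
        a <- matrix(sample.int(K, 2 * n, replace = TRUE, prob = p), ncol = 2)
        if (spec$missing_rate > 0) {
          drop <- stats::runif(n) < spec$missing_rate
          a[drop, ] <- NA_integer_
        }
        a
      })
      calls[row0 + seq_len(n), l, ] <- g
      row0 <- row0 + n
    }
  }
  genotype_dataset(ids, sites, loci, calls)
}

#' Simulate aligned mtDNA haplotype samples for multiple sites
#'
#' Builds a random root sequence, derives a pool of shared haplotypes and
#' per-site private haplotypes by placing `divergence` substitutions at
#' haplotype-specific positions (so all haplotypes are mutually distinct
#' whenever `divergence >= 1`), then samples per-site haplotype frequencies
#' with two prevalent shared haplotypes -- the composition seen at connected
#' breeding sites.  Sites listed in `isolate_sites` instead concentrate at
#' least `isolate_weight` of their sample on a single private haplotype,
#' emulating a strongly drifted isolate.
#'
#' @param n_per_site named integer vector: samples per site
#' @param shared_pool number of haplotypes shared across sites
#' @param private_pool private haplotypes per site
#' @param divergence substitutions separating each haplotype from the root
#' @param seq_length alignment length in bp
#' @param isolate_sites site names treated as drifted isolates
#' @param isolate_weight minimum fraction of an isolate's sample carrying its
#'   dominant haplotype (allocated deterministically as
#'   `ceiling(weight * n)`)
#' @param seed integer seed
#' @return a [seq_alignment()]
#' @export
simulate_mtdna_haplotypes <- function(n_per_site, shared_pool = 8,
                                      private_pool = 2, divergence = 3,
                                      seq_length = 475, isolate_sites = character(),
                                      isolate_weight = 0.95, seed = 1L) {
  if (divergence < 0) stop("divergence must be >= 0")
  site_names <- names(n_per_site)
  if (is.null(site_names)) site_names <- sprintf("site%02d", seq_along(n_per_site))
  n_hap <- shared_pool + private_pool * length(n_per_site)
  if (divergence > 0 && n_hap * divergence > seq_length) {
    stop("haplotype pool too large: need distinct substitution positions per haplotype")
  }
  withr::with_seed(sub_seed(seed, "mtdna"), {
    root <- sample(c("A", "C", "G", "T"), seq_length, replace = TRUE)
    mutate <- function(pos) {
      s <- root
      for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
      paste(s, collapse = "")
    }
    pos_pool <- if (divergence > 0) {
      split(sample.int(seq_length, n_hap * divergence),
            rep(seq_len(n_hap), each = divergence))
    } else {
      rep(list(integer()), n_hap)
    }
    haps <- vapply(pos_pool, mutate, character(1))
    shared <- haps[seq_len(shared_pool)]

    ids <- character(0); sites <- character(0); seqs <- character(0)
    for (k in seq_along(n_per_site)) {
      sname <- site_names[k]
      n <- n_per_site[[k]]
      priv <- haps[shared_pool + (k - 1) * private_pool + seq_len(private_pool)]
      pool <- c(shared, priv)
      if (sname %in% isolate_sites) {
        n_major <- min(n, ceiling(isolate_weight * n))
        rest <- if (n > n_major) {
          sample(pool[-length(pool)], n - n_major, replace = TRUE)
        } else character(0)
        draw <- c(rep(pool[length(pool)], n_major), rest)
      } else {
        # two prevalent shared haplotypes, a tail of rarer ones
        w <- c(8, 6, rep(0.6, max(0, shared_pool - 2)), rep(0.4, private_pool))
        w <- w[seq_along(pool)]
        draw <- sample(pool, n, replace = TRUE, prob = w / sum(w))
      }
      ids <- c(ids, sprintf("%s_%02d", sname, seq_len(n)))
      sites <- c(sites, rep(sname, n))
      seqs <- c(seqs, draw)
    }
    seq_alignment(ids, sites, seqs)
  })
}

#' Movement regime spec for one simulated seal
#'
#' Encodes the two-regime seasonal pattern seen in tracked ringed seals: a
#' near-site winter regime (isotropic Gaussian scatter of scale
#' `winter_sd_km` around the capture site during the ice-bound months) and a
#' long-range summer regime (distance from site drawn around
#' `summer_mean_km` along a persistent random bearing during the open-water
#' months), with Argos-like isotropic position noise added to every fix.
#'
#' @param capture_site `c(lat, lon)` of the breeding/capture site
#' @param winter_sd_km winter scatter scale (km), > 0
#' @param summer_mean_km,summer_sd_km summer distance distribution (km)
#' @param summer_months calendar months (1-12) in the long-range regime;
#'   the remaining months form the near-site regime
#' @param obs_per_month positions generated per calendar month
#' @param argos_noise_km isotropic position noise SD (km)
#' @param start_date first day of the simulated year (UTC)
#' @param n_months number of months simulated
#' @param seed integer seed
#' @return object of class `movement_regime_spec`
#' @export
movement_regime_spec <- function(capture_site = c(70.5, -156.8),
                                 winter_sd_km = 30, summer_mean_km = 400,
                                 summer_sd_km = 200, summer_months = 6:11,
                                 obs_per_month = 10, argos_noise_km = 2.5,
                                 start_date = as.Date("2005-12-01"),
                                 n_months = 12, seed = 1L) {
  stopifnot(winter_sd_km > 0, summer_sd_km > 0, argos_noise_km >= 0,
            all(summer_months %in% 1:12), obs_per_month >= 1)
  structure(list(capture_site = capture_site, winter_sd_km = winter_sd_km,
                 summer_mean_km = summer_mean_km, summer_sd_km = summer_sd_km,
                 summer_months = as.integer(summer_months),
                 obs_per_month = as.integer(obs_per_month),
                 argos_noise_km = argos_noise_km,
                 start_date = as.Date(start_date),
                 n_months = as.integer(n_months), seed = as.integer(seed)),
            class = "movement_regime_spec")
}

# local equirectangular km -> degrees at the capture latitude
km_to_deg <- function(dx_km, dy_km, lat0) {
  list(dlat = dy_km / 111.32,
       dlon = dx_km / (111.32 * cos(lat0 * pi / 180)))
}

#' Simulate a satellite telemetry track under a two-regime seasonal model
#'
#' The seal's distance from its capture site follows a continuous
#' piecewise-linear excursion path: zero at the midpoint of every
#' near-site month and a month-specific draw around `summer_mean_km`
#' (AR(1)-correlated across consecutive summer months) at the midpoint of
#' every long-range month, travelled along one persistent random bearing.
#' Local scatter of scale `winter_sd_km` and Argos-like position noise are
#' added to every fix, and fix times are evenly spaced with jitter.  The
#' continuous path keeps implied travel speeds realistic, so the speed
#' filter removes (essentially) only injected outliers.
#'
#' @param spec a [movement_regime_spec()]
#' @param animal_id identifier for the generated track
#' @param inject_outliers number of teleport points (~500 km displaced, 1 h
#'   apart from a neighbour) appended to exercise the speed filter
#' @return a [telemetry_track()]
#' @export
simulate_track <- function(spec, animal_id = "sim01", inject_outliers = 0L) {
  stopifnot(inherits(spec, "movement_regime_spec"))
  lat0 <- spec$capture_site[1]; lon0 <- spec$capture_site[2]
  withr::with_seed(sub_seed(spec$seed, "track", animal_id), {
    bearing <- stats::runif(1, 0, 2 * pi)   # persistent summer direction
    t0 <- as.POSIXct(paste(spec$start_date, "00:00:00"), tz = "UTC")
    month_start <- seq(t0, by = "month", length.out = spec$n_months + 1)
    month_num <- as.integer(format(month_start[seq_len(spec$n_months)], "%m"))
    month_len <- as.numeric(difftime(month_start[-1],
                                     month_start[-length(month_start)],
                                     units = "secs"))
    # radial knots at month midpoints; AR(1) across summer months
    knot_t <- as.numeric(month_start[seq_len(spec$n_months)]) + month_len / 2
    knot_r <- numeric(spec$n_months)
    prev <- spec$summer_mean_km
    for (m in seq_len(spec$n_months)) {
      if (month_num[m] %in% spec$summer_months) {
        prev <- spec$summer_mean_km +
          0.6 * (prev - spec$summer_mean_km) +
          stats::rnorm(1, 0, spec$summer_sd_km * 0.8)
        knot_r[m] <- max(0, prev)
      } else {
        knot_r[m] <- 0
        prev <- spec$summer_mean_km
      }
    }
    rows <- list()
    for (m in seq_len(spec$n_months)) {
      n <- spec$obs_per_month
      off <- ((seq_len(n) - 0.5) / n + stats::runif(n, -0.2, 0.2) / n) *
        month_len[m]
      tt <- month_start[m] + sort(pmin(pmax(off, 0), month_len[m]))
      r <- stats::approx(knot_t, knot_r, xout = as.numeric(tt), rule = 2)$y
      dx <- r * cos(bearing) + stats::rnorm(n, 0, spec$winter_sd_km) +
        stats::rnorm(n, 0, spec$argos_noise_km)
      dy <- r * sin(bearing) + stats::rnorm(n, 0, spec$winter_sd_km) +
        stats::rnorm(n, 0, spec$argos_noise_km)
      dd <- km_to_deg(dx, dy, lat0)
      rows[[m]] <- data.frame(timestamp = tt, lat = lat0 + dd$dlat,
                              lon = lon0 + dd$dlon)
    }
    rec <- do.call(rbind, rows)
    if (inject_outliers > 0) {
      pick <- sort(sample.int(nrow(rec) - 1, inject_outliers))
      out <- rec[pick, , drop = FALSE]
      out$timestamp <- out$timestamp + 3600           # one hour later
      dd <- km_to_deg(500, 0, lat0)                   # 500 km east: > 2 m/s
      out$lon <- out$lon + dd$dlon
      rec <- rbind(rec, out)
    }
    tr <- telemetry_track(animal_id, rec, capture_site = spec$capture_site)
    tr
  })
}

#' Simulate an hourly haulout (dry-time) series
#'
#' Hourly dry fractions are elevated to `peak_dry` within `dry_window`
#' (hours of day, 0-23) and sit at `base_dry` outside it, with Gaussian
#' noise added wherever the mean level is positive, clipped to `[0, 1]`.
#' A zero mean level yields an exact 0 (the sensor is wet all hour).
#'
#' @param days number of days
#' @param dry_window integer hours of day with elevated haulout
#' @param base_dry baseline dry fraction in `[0, 1]`
#' @param peak_dry dry fraction within the window
#' @param noise_sd Gaussian noise SD
#' @param start_date first day (UTC)
#' @param seed integer seed
#' @return data frame with `timestamp` (hourly POSIXct) and `dry_fraction`
#' @export
simulate_haulout <- function(days, dry_window = 4:18, base_dry = 0.1,
                             peak_dry = 0.65, noise_sd = 0.08,
                             start_date = as.Date("2006-05-01"), seed = 1L) {
  stopifnot(base_dry >= 0, base_dry <= 1, days >= 1)
  withr::with_seed(sub_seed(seed, "haulout"), {
    t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
    ts <- t0 + 3600 * (seq_len(days * 24) - 1)
    hour <- as.integer(format(ts, "%H"))
    mu <- ifelse(hour %in% dry_window, peak_dry, base_dry)
    eps <- stats::rnorm(length(mu), 0, noise_sd)
    dry <- ifelse(mu > 0, pmin(1, pmax(0, mu + eps)), 0)
    data.frame(timestamp = ts, dry_fraction = dry)
  })
}
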