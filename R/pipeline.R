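#' Assemble a run configuration
#'
#' A run configuration names the inputs (file paths, or simulation specs to
#' generate them) and the test parameters for every stage.  Any of the
#' three input blocks may be omitted, in which case the corresponding
#' stages are skipped.
#'
#' @param genotypes a GenePop path, a [genotype_dataset()], or an
#'   [island_model_spec()]
#' @param mtdna named list of marker blocks, each a list with `alignment`
#'   (a path or [seq_alignment()]) and `alpha` (gamma shape for TN93)
#' @param telemetry list of [telemetry_track()] (or a CSV path)
#' @param haulout data frame of hourly dry fractions (or a CSV path)
#' @param n_perm named overrides for permutation counts: `amova` (16000),
#'   `kst` (5000), `fst` (1000), `hwe` (999), `ld` (999), `season` (10000)
#' @param alpha pairwise decision level
#' @param bonferroni_sig_figs significant figures for reported adjusted
#'   alpha levels
#' @param std_N standardized rarefaction size
#' @param rar_reps rarefaction subsampling replicates
#' @param v_max speed-filter threshold (m/s)
#' @param seed master seed; every stochastic stage receives a derived
#'   sub-seed
#' @param out_dir output directory for result tables
#' @return object of class `run_config`
#' @export
run_config <- function(genotypes = NULL, mtdna = NULL, telemetry = NULL,
                       haulout = NULL, n_perm = list(), alpha = 0.05,
                       bonferroni_sig_figs = 1, std_N = 20, rar_reps = 1000,
                       v_max = 2.0, seed = 1L, out_dir = tempfile("sealmix_run")) {
  np <- utils::modifyList(list(amova = 16000, kst = 5000, fst = 1000,
                               hwe = 999, ld = 999, season = 10000), n_perm)
  structure(list(genotypes = genotypes, mtdna = mtdna, telemetry = telemetry,
                 haulout = haulout, n_perm = np, alpha = alpha,
                 bonferroni_sig_figs = bonferroni_sig_figs, std_N = std_N,
                 rar_reps = rar_reps, v_max = v_max, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; input blocks
#' give file paths.
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

# write a result table with the package/seed provenance comment line
write_result_csv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sealmix %s seed=%d",
                     as.character(utils::packageVersion("sealmix")), seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

resolve_genotypes <- function(x) {
  if (is.null(x)) NULL
  else if (inherits(x, "genotype_dataset")) x
  else if (inherits(x, "island_model_spec")) simulate_island_genotypes(x)
  else read_genepop(x)
}

resolve_alignment <- function(x) {
  if (inherits(x, "seq_alignment")) x else read_fasta_alignment(x)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: duplicate-genotype screening
#' (redundant genotypes are removed before any genetic analysis, keeping
#' the first-seen copy), within-site diversity, between-site
#' differentiation, panmixia screening per marker, and telemetry/haulout
#' summaries.  Each stage writes a CSV result table under
#' `config$out_dir`; a manifest records the seed, inputs, stage timings and
#' output digests.
#'
#' @param config a [run_config()]
#' @param keep_duplicates `"first"` or `"least_missing"`
#' @return list with the stage results, the paths of written tables, and
#'   the manifest (also written as `manifest.yaml`)
#' @export
run_pipeline <- function(config, keep_duplicates = c("first", "least_missing")) {
  stopifnot(inherits(config, "run_config"))
  keep_duplicates <- match.arg(keep_duplicates)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  results <- list()
  tables <- character()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  emit <- function(df, file) {
    path <- file.path(config$out_dir, file)
    write_result_csv(df, path, seed)
    tables <<- c(tables, path)
  }

  ds <- resolve_genotypes(config$genotypes)
  if (!is.null(ds)) {
    dedup <- stage("duplicates", remove_duplicate_genotypes(
      ds, keep = keep_duplicates))
    emit(dedup$flagged, "duplicates.csv")
    ds <- dedup$dataset
    results$duplicates <- dedup

    results$diversity <- stage("diversity", {
      het <- heterozygosity(ds)
      hwe <- do.call(rbind, lapply(seq_len(nrow(het)), function(r) {
        if (het$n[r] < 3 || !isTRUE(het$polymorphic[r])) {
          return(data.frame(site = het$site[r], locus = het$locus[r],
                            p = NA_real_, p_homozygote_excess = NA_real_))
        }
        t <- hwe_test(ds, het$site[r], het$locus[r],
                      n_perm = config$n_perm$hwe, seed = sub_seed(seed, "hwe"))
        data.frame(site = het$site[r], locus = het$locus[r], p = t$p,
                   p_homozygote_excess = t$p_homozygote_excess)
      }))
      adj_hwe <- bonferroni_alpha(0.05, sum(!is.na(hwe$p)),
                                  config$bonferroni_sig_figs)
      het <- merge(het, hwe, by = c("site", "locus"), sort = FALSE)
      lp <- if (length(ds$loci) >= 2) utils::combn(ds$loci, 2) else NULL
      ld <- if (is.null(lp)) NULL else do.call(rbind, lapply(
        unique(ds$sites), function(s) {
          do.call(rbind, lapply(seq_len(ncol(lp)), function(c_i) {
            t <- ld_test(ds, s, lp[, c_i], n_perm = config$n_perm$ld,
                         seed = sub_seed(seed, "ld"))
            data.frame(site = s, locus_a = lp[1, c_i], locus_b = lp[2, c_i],
                       G = t$statistic, p = t$p)
          }))
        }))
      adj_ld <- if (is.null(ld)) NULL else {
        bonferroni_alpha(0.05, max(1, sum(!is.na(ld$p))),
                         config$bonferroni_sig_figs)
      }
      rar <- rarefied_allelic_richness(ds, config$std_N,
                                       n_reps = config$rar_reps,
                                       seed = sub_seed(seed, "rar"))
      list(site_locus = het, ld = ld, rarefaction = rar,
           adjusted_alpha_hwe = adj_hwe, adjusted_alpha_ld = adj_ld)
    })
    emit(results$diversity$site_locus, "diversity_site_locus.csv")
    if (!is.null(results$diversity$ld)) {
      emit(results$diversity$ld, "ld_tests.csv")
    }
    emit(as.data.frame(results$diversity$rarefaction), "rarefaction.csv")

    results$differentiation <- stage("differentiation", {
      sites <- unique(ds$sites)
      prs <- utils::combn(sites, 2)
      fst <- do.call(rbind, lapply(seq_len(ncol(prs)), function(c_i) {
        pr <- prs[, c_i]
        t <- fst_permutation_test(ds, pr, n_perm = config$n_perm$fst,
                                  seed = sub_seed(seed, "fst", pr[1], pr[2]))
        data.frame(site_a = pr[1], site_b = pr[2], theta = t$statistic,
                   p = t$p)
      }))
      dm <- pairwise_genotype_distances(ds, "allele_count_diff")
      am <- amova(dm, ds$sites, n_perm = config$n_perm$amova,
                  seed = sub_seed(seed, "amova"))
      apd <- avg_pairwise_differences(dm, ds$sites)
      list(pairwise_fst = fst, amova_microsat = am, avg_pairwise = apd)
    })
    emit(results$differentiation$pairwise_fst, "pairwise_fst.csv")
    am <- results$differentiation$amova_microsat
    emit(cbind(marker = am$marker, am$table,
               phi_st = am$phi_st, p = am$p), "amova_microsat.csv")

    results$panmixia_microsat <- stage("panmixia_microsat", panmixia_screen(
      pairwise_genotype_distances(ds, "genotype_smouse_peakall"), ds$sites,
      n_perm = config$n_perm$kst, seed = sub_seed(seed, "kst-usat"),
      alpha = config$alpha))
    emit(cbind(results$panmixia_microsat$table, marker = "microsatellite"),
         "panmixia_microsat.csv")
  }

  if (!is.null(config$mtdna)) {
    for (mk in names(config$mtdna)) {
      blk <- config$mtdna[[mk]]
      aln <- resolve_alignment(blk$alignment)
      dm <- pairwise_sequence_distances(aln, alpha = blk$alpha)
      results[[paste0("haplotypes_", mk)]] <- haplotype_frequencies(aln)
      am <- stage(paste0("amova_", mk),
                  amova(dm, aln$sites, n_perm = config$n_perm$amova,
                        seed = sub_seed(seed, "amova", mk)))
      results[[paste0("amova_", mk)]] <- am
      emit(cbind(marker = mk, am$table, phi_st = am$phi_st, p = am$p),
           sprintf("amova_%s.csv", mk))
      scr <- stage(paste0("panmixia_", mk), panmixia_screen(
        dm, aln$sites, n_perm = config$n_perm$kst,
        seed = sub_seed(seed, "kst", mk), alpha = config$alpha))
      results[[paste0("panmixia_", mk)]] <- scr
      emit(cbind(scr$table, marker = mk), sprintf("panmixia_%s.csv", mk))
    }
  }

  if (!is.null(config$telemetry)) {
    tracks <- config$telemetry
    if (is.character(tracks)) tracks <- read_telemetry_csv(tracks)
    if (inherits(tracks, "telemetry_track")) tracks <- list(tracks)
    results$telemetry <- stage("telemetry", {
      filtered <- lapply(tracks, speed_filter, v_max = config$v_max)
      seas <- do.call(rbind, lapply(filtered, function(tr) {
        s <- seasonal_distance_test(tr, n_perm = config$n_perm$season,
                                    seed = sub_seed(seed, "season", tr$animal_id))
        data.frame(animal_id = s$animal_id,
                   n_obs = nrow(tr$records),
                   ice_mean = s$ice_bound["mean"], ice_max = s$ice_bound["max"],
                   open_mean = s$open_water["mean"],
                   open_max = s$open_water["max"], p = s$p)
      }))
      list(filtered = filtered, seasonal = seas,
           monthly = monthly_localization(filtered))
    })
    emit(results$telemetry$seasonal, "telemetry_seasonal.csv")
    emit(results$telemetry$monthly, "monthly_localization.csv")
  }

  if (!is.null(config$haulout)) {
    series <- config$haulout
    if (is.character(series)) {
      series <- utils::read.csv(series, comment.char = "#")
    }
    results$haulout <- stage("haulout", haulout_summary(series))
    hs <- results$haulout
    emit(data.frame(hour = hs$hours, exceedance = hs$exceedance,
                    mean_dry = hs$mean_dry, range_dry = hs$range_dry),
         "haulout_summary.csv")
  }

  manifest <- list(
    package = "sealmix",
    version = as.character(utils::packageVersion("sealmix")),
    seed = seed,
    stages = names(timings),
    timings_s = timings,
    tables = basename(tables),
    table_md5 = as.list(stats::setNames(unname(tools::md5sum(tables)),
                                        basename(tables))))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  list(results = results, tables = tables, manifest = manifest)
}
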