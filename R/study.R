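#' Sampling design of the emulated multi-subspecies ringed-seal study
#'
#' Eleven breeding sites in three groups: nine Arctic sites (Chukchi,
#' Western Beaufort and Eastern Beaufort regions) forming a large,
#' effectively panmictic group; a Baltic site connected to the Arctic by
#' on the order of 10-45 migrants per generation (island-model equilibrium
#' `F = 1/(1 + 4Nm)` with `Nm = 20`); and a strongly drifted Lake Saimaa
#' isolate.  Microsatellite sample sizes total 354 individuals; the mtDNA
#' columns give the per-site sequence counts for the COI and control-region
#' alignments.
#'
#' @return data frame with columns `site`, `group`, `n_microsat`, `n_coi`,
#'   `n_cr`, `target_fst`
#' @export
study_sites <- function() {
  data.frame(
    site = c("Kotzebue", "PeardBay", "Barrow", "Oliktok", "Prudhoe",
             "Kaktovik", "Paktoa", "Tuktoyaktuk", "Ulukhaktok",
             "Baltic", "Saimaa"),
    group = c("Chukchi", "Chukchi", "WBeaufort", "WBeaufort", "WBeaufort",
              "WBeaufort", "EBeaufort", "EBeaufort", "EBeaufort",
              "Baltic", "Saimaa"),
    n_microsat = c(20L, 40L, 30L, 25L, 30L, 25L, 35L, 60L, 40L, 27L, 22L),
    n_coi = c(6L, 17L, 0L, 1L, 0L, 0L, 14L, 27L, 15L, 11L, 22L),
    n_cr = c(4L, 17L, 0L, 1L, 0L, 0L, 14L, 27L, 15L, 11L, 10L),
    target_fst = c(rep(0.005, 9), 1 / (1 + 4 * 20), 0.75))
}

#' Gamma shape defaults for the two mtDNA regions
#' @return named numeric vector (`coi`, `cr`)
#' @export
study_mtdna_alpha <- function() c(coi = 0.25103, cr = 0.164)

#' Microsatellite simulation spec for the emulated study
#'
#' Nine loci with 4-15 alleles, per-site sample sizes and drift levels from
#' [study_sites()].
#'
#' @param seed integer seed
#' @param missing_rate per-genotype missingness
#' @return an [island_model_spec()]
#' @export
study_genotype_spec <- function(seed = 1L, missing_rate = 0.02) {
  st <- study_sites()
  sp <- island_model_spec(
    n_sites = nrow(st), n_per_site = st$n_microsat, n_loci = 9,
    n_alleles_per_locus = c(8, 12, 15, 6, 10, 9, 4, 11, 7),
    target_fst = st$target_fst, site_names = st$site,
    missing_rate = missing_rate, seed = seed)
  sp
}

#' Simulated genotype dataset for the emulated study, with group labels
#' @inheritParams study_genotype_spec
#' @return a [genotype_dataset()] with regional `groups`
#' @export
study_genotypes <- function(seed = 1L, missing_rate = 0.02) {
  st <- study_sites()
  ds <- simulate_island_genotypes(study_genotype_spec(seed, missing_rate))
  ds$groups <- st$group[match(ds$sites, st$site)]
  ds
}

#' Simulated mtDNA alignment for one region of the emulated study
#'
#' COI: moderate shared haplotype pool with two prevalent haplotypes at the
#' connected sites and a Saimaa isolate carrying one dominant private
#' haplotype.  CR: larger haplotype pool (the control region is
#' hypervariable).  Sites with fewer than one sequence are dropped.
#'
#' @param region `"coi"` or `"cr"`
#' @param seed integer seed
#' @return a [seq_alignment()] of 475-bp sequences
#' @export
study_mtdna_alignment <- function(region = c("coi", "cr"), seed = 1L) {
  region <- match.arg(region)
  st <- study_sites()
  n <- if (region == "coi") st$n_coi else st$n_cr
  names(n) <- st$site
  n <- n[n > 0]
  pools <- if (region == "coi") c(shared = 12, private = 2, div = 3)
           else c(shared = 20, private = 3, div = 2)
  simulate_mtdna_haplotypes(
    n, shared_pool = pools[["shared"]], private_pool = pools[["private"]],
    divergence = pools[["div"]], seq_length = 475,
    isolate_sites = "Saimaa", seed = sub_seed(seed, "mtdna", region))
}
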