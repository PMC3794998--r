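#' Diploid multi-locus genotype dataset
#'
#' The central container for microsatellite data: each individual carries an
#' unordered allele pair (positive integer codes) at each locus, a sampling
#' site label, and optionally a higher-level group label (subspecies or
#' region).  Missing data are whole-genotype per individual x locus: a
#' half-called genotype is rejected at construction.
#'
#' @param ids character vector of individual identifiers (made unique)
#' @param sites per-individual site label
#' @param loci ordered locus names
#' @param calls integer array `n_ind x n_loci x 2`; `NA` pairs mark missing
#'   genotypes
#' @param groups optional per-individual higher-level label; defaults to the
#'   site label
#' @return object of class `genotype_dataset`
#' @export
genotype_dataset <- function(ids, sites, loci, calls, groups = sites) {
  ids <- make.unique(as.character(ids))
  sites <- as.character(sites)
  groups <- as.character(groups)
  loci <- as.character(loci)
  stopifnot(length(sites) == length(ids), length(groups) == length(ids))
  if (!is.array(calls) || length(dim(calls)) != 3 ||
      dim(calls)[1] != length(ids) || dim(calls)[2] != length(loci) ||
      dim(calls)[3] != 2) {
    stop("`calls` must be an n_ind x n_loci x 2 array")
  }
  storage.mode(calls) <- "integer"
  half <- xor(is.na(calls[, , 1, drop = FALSE]), is.na(calls[, , 2, drop = FALSE]))
  if (any(half)) stop("half-called genotypes are not allowed (one allele NA)")
  if (any(calls <= 0, na.rm = TRUE)) stop("allele codes must be positive integers")
  dimnames(calls) <- list(ids, loci, NULL)
  structure(list(ids = ids, sites = sites, groups = groups,
                 loci = loci, calls = calls),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals, %d loci, %d sites (%d groups)\n",
              length(x$ids), length(x$loci),
              length(unique(x$sites)), length(unique(x$groups))))
  miss <- mean(is.na(x$calls[, , 1]))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals in a genotype dataset
#' @param ds a `genotype_dataset`
#' @return integer count
#' @export
n_individuals <- function(ds) length(ds$ids)

#' Subset a genotype dataset by individual
#' @param ds a `genotype_dataset`
#' @param keep logical or integer index over individuals
#' @return a `genotype_dataset` with the selected individuals
#' @export
subset_individuals <- function(ds, keep) {
  genotype_dataset(ds$ids[keep], ds$sites[keep], ds$loci,
                   ds$calls[keep, , , drop = FALSE], ds$groups[keep])
}

#' Read a GenePop genotype file
#'
#' Parses the GenePop dialect: a title line, locus names (one per line or a
#' single comma-separated line), then `POP` blocks of individuals.  Both the
#' comma-after-id and whitespace-separated variants are accepted; genotypes
#' may use 2- or 3-digit allele coding (consistently within a file).
#' `"0000"`/`"000000"` decode to missing.  Site labels are taken from the
#' last individual label of each block (the GenePop convention) or, when
#' labels are absent, `pop<k>`.
#'
#' @param path file path
#' @return a [genotype_dataset()]
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a GenePop file: too few lines")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a GenePop file: no POP line")
  header <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]

  block <- cumsum(is_pop)
  n_pop <- max(block)
  recs <- list()
  width <- NA_integer_
  for (i in seq_along(lines)[-seq_len(first_pop - 1)]) {
    if (is_pop[i]) next
    line <- lines[i]
    if (grepl(",", line)) {
      parts <- strsplit(line, ",")[[1]]
      id <- trimws(parts[1])
      gfields <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    } else {
      toks <- strsplit(trimws(line), "\\s+")[[1]]
      id <- toks[1]
      gfields <- toks[-1]
    }
    gfields <- gfields[nzchar(gfields)]
    if (length(gfields) != length(loci)) {
      stop(sprintf("line %d: %d genotype fields for %d loci",
                   i, length(gfields), length(loci)))
    }
    if (!all(grepl("^[0-9]+$", gfields))) {
      stop(sprintf("line %d: non-numeric genotype field", i))
    }
    w <- unique(nchar(gfields))
    if (length(w) > 1 || !(w %in% c(4L, 6L))) {
      stop(sprintf(
        "line %d: mixed genotype field widths (must be uniformly 4 or 6 digits)",
        i))
    }
    if (is.na(width)) width <- w
    if (w != width) stop(sprintf("line %d: mixed allele-code widths in file", i))
    d <- width / 2L
    a1 <- as.integer(substr(gfields, 1L, d))
    a2 <- as.integer(substr(gfields, d + 1L, width))
    miss <- a1 == 0L & a2 == 0L
    if (any(xor(a1 == 0L, a2 == 0L))) {
      stop(sprintf("line %d: half-called genotype (one allele coded 0)", i))
    }
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    recs[[length(recs) + 1L]] <- list(id = id, pop = block[i], a1 = a1, a2 = a2)
  }
  if (!length(recs)) stop("GenePop file contains no individuals")

  n <- length(recs)
  calls <- array(NA_integer_, dim = c(n, length(loci), 2))
  ids <- character(n)
  popidx <- integer(n)
  for (k in seq_len(n)) {
    ids[k] <- recs[[k]]$id
    popidx[k] <- recs[[k]]$pop
    calls[k, , 1] <- recs[[k]]$a1
    calls[k, , 2] <- recs[[k]]$a2
  }
  # site label = last individual label in the block, else pop<k>
  site_names <- vapply(seq_len(n_pop), function(p) {
    lab <- ids[popidx == p]
    lab <- lab[length(lab)]
    if (nzchar(lab)) lab else paste0("pop", p)
  }, character(1))
  site_names <- make.unique(site_names)
  genotype_dataset(ids, site_names[popidx], loci, calls)
}

#' Write a GenePop genotype file
#'
#' Always emits 3-digit allele coding with the comma-after-id layout; missing
#' genotypes are written `000000`.  Site labels are preserved by writing the
#' site name as every individual's label within its block, so
#' `read_genepop(write_genepop(ds))` recovers sites and calls.
#'
#' @param ds a [genotype_dataset()]
#' @param path output file path
#' @param title title line (first line of the file)
#' @return `path`, invisibly
#' @export
write_genepop <- function(ds, path, title = "sealmix genotypes") {
  if (any(ds$calls > 999, na.rm = TRUE)) stop("allele codes exceed 3 digits")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(ds$loci, con)
  for (s in unique(ds$sites)) {
    writeLines("POP", con)
    for (k in which(ds$sites == s)) {
      g <- ds$calls[k, , , drop = FALSE]
      a1 <- g[1, , 1]
      a2 <- g[1, , 2]
      a1[is.na(a1)] <- 0L
      a2[is.na(a2)] <- 0L
      writeLines(sprintf("%s ,  %s", s,
                         paste0(sprintf("%03d", a1), sprintf("%03d", a2),
                                collapse = " ")), con)
    }
  }
  invisible(path)
}
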