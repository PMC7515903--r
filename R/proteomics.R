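## In-silico proteolytic digestion and emPAI quantification.
##
## The digestion follows the trypsin rule (cleavage after K or R, not
## before P) with up to two missed cleavages; a Lys-C pre-digestion adds
## no cleavage sites under this convention because its K sites are a
## subset of trypsin's. Cys carries a fixed carbamidomethyl
## modification. A peptide is observable when some allowed charge state
## puts its m/z inside the instrument scan range.

## monoisotopic residue masses (Da)
.AA_MONO <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
              V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
              I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
              K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
              F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
.MASS_WATER <- 18.010565
.MASS_PROTON <- 1.007276
.MASS_CAM <- 57.02146  # carbamidomethyl on Cys (fixed)

#' Monoisotopic peptide mass
#'
#' Residue masses plus water, plus one fixed carbamidomethyl (+57.02146
#' Da) per cysteine. Peptides containing non-standard residues get `NA`.
#'
#' @param peptides character vector of peptide sequences.
#' @param carbamidomethyl apply the fixed Cys modification (default
#'   TRUE).
#' @return numeric vector of masses (Da).
#' @export
peptide_mass <- function(peptides, carbamidomethyl = TRUE) {
  vapply(peptides, function(p) {
    aa <- s2c(toupper(p))
    m <- .AA_MONO[aa]
    if (anyNA(m)) return(NA_real_)
    sum(m) + .MASS_WATER +
      if (carbamidomethyl) .MASS_CAM * sum(aa == "C") else 0
  }, numeric(1), USE.NAMES = FALSE)
}

#' Peptide m/z at a charge state
#' @param mass monoisotopic mass (Da).
#' @param z charge.
#' @return m/z value(s).
#' @export
peptide_mz <- function(mass, z) (mass + z * .MASS_PROTON) / z

#' In-silico Lys-C/trypsin digestion
#'
#' Cleaves after K or R except before P and enumerates all peptides
#' with at most `max_missed` internal cleavage sites. Peptides with
#' non-standard residues are flagged and carry `NA` mass.
#'
#' @param protein amino-acid string.
#' @param max_missed maximum missed cleavages (default 2).
#' @return data.frame: peptide, start, end (1-based, inclusive),
#'   missed, mass, nonstandard.
#' @export
digest <- function(protein, max_missed = 2L) {
  x <- s2c(toupper(protein))
  n <- length(x)
  if (!n) stop("empty protein")
  site <- which(x %in% c("K", "R"))
  site <- site[site < n]            # a C-terminal K/R is not internal
  site <- site[x[site + 1L] != "P"] # trypsin does not cleave K/R-P
  starts <- c(1L, site + 1L)
  ends <- c(site, n)
  nf <- length(starts)
  rows <- list()
  for (i in seq_len(nf)) {
    for (j in i:min(nf, i + max_missed)) {
      pep <- substr(protein, starts[i], ends[j])
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, start = starts[i], end = ends[j],
        missed = j - i)
    }
  }
  out <- do.call(rbind, rows)
  out$mass <- peptide_mass(out$peptide)
  out$nonstandard <- is.na(out$mass)
  out
}

#' Filter peptides to the observable set
#'
#' A peptide is observable when at least one allowed charge state puts
#' its m/z inside `mz_range`. Distinct by sequence; non-standard
#' peptides are never observable.
#'
#' @param peptides character vector or a [digest()] data.frame.
#' @param mz_range instrument scan range (default m/z 400-1500).
#' @param charges allowed charge states (default 2 and 3; the survey
#'   selects multiply charged ions).
#' @return data.frame: peptide, mass, observable, plus one `mz<z>`
#'   column per charge, one row per distinct sequence.
#' @export
observable_filter <- function(peptides, mz_range = c(400, 1500),
                              charges = c(2L, 3L)) {
  seqs <- if (is.data.frame(peptides)) peptides$peptide else peptides
  seqs <- unique(seqs)
  if (!length(seqs))
    return(data.frame(peptide = character(0), mass = numeric(0),
                      observable = logical(0)))
  mass <- peptide_mass(seqs)
  out <- data.frame(peptide = seqs, mass = mass)
  obs <- rep(FALSE, length(seqs))
  for (z in charges) {
    mz <- peptide_mz(mass, z)
    out[[paste0("mz", z)]] <- mz
    obs <- obs | (!is.na(mz) & mz >= mz_range[1L] & mz <= mz_range[2L])
  }
  out$observable <- obs
  out
}

#' Observable peptide set of a protein
#'
#' Distinct fully cleaved peptides passing the observability filter
#' (missed-cleavage forms are excluded from the observable count by the
#' emPAI convention unless `include_missed`).
#' @param protein amino-acid string.
#' @param include_missed include missed-cleavage peptides.
#' @inheritParams observable_filter
#' @param max_missed missed cleavages enumerated when `include_missed`.
#' @return character vector of distinct observable peptide sequences.
#' @export
observable_peptides <- function(protein, mz_range = c(400, 1500),
                                charges = c(2L, 3L),
                                include_missed = FALSE,
                                max_missed = 2L) {
  dg <- digest(protein, max_missed = if (include_missed) max_missed
                                     else 0L)
  ob <- observable_filter(dg, mz_range = mz_range, charges = charges)
  ob$peptide[ob$observable]
}

#' Exponentially modified protein abundance index
#'
#' `empai = 10^(n_observed / n_observable) - 1`.
#' @param n_observed distinct observable peptides actually identified.
#' @param n_observable distinct peptides passing the observability
#'   filter (must be >= 1).
#' @return numeric emPAI value(s) in `[0, 9]`.
#' @export
empai <- function(n_observed, n_observable) {
  if (any(n_observable < 1L)) stop("n_observable must be >= 1")
  if (any(n_observed < 0L) || any(n_observed > n_observable))
    stop("need 0 <= n_observed <= n_observable")
  10^(n_observed / n_observable) - 1
}

#' Match observed peptides to a protein database
#'
#' Observed peptides are mapped to proteins by exact sequence match
#' against each protein's observable set; peptides matching multiple
#' proteins are counted for each and flagged shared. Counting is by
#' distinct sequence, which makes emPAI invariant to the repeat copy
#' number of a protein (a repeat-unit peptide occurring many times in
#' one protein is one observable peptide).
#'
#' @param observations data.frame with columns region, peptide, count
#'   (a TSV path is accepted).
#' @param proteins named character vector of protein sequences.
#' @inheritParams observable_peptides
#' @return list: `matched` (region, protein, peptide, count, shared),
#'   `unmatched` (character vector), `observable_sets` (list).
#' @export
match_observations <- function(observations, proteins,
                               mz_range = c(400, 1500),
                               charges = c(2L, 3L)) {
  if (is.character(observations) && length(observations) == 1L)
    observations <- read.table(observations, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  stopifnot(all(c("region", "peptide", "count") %in%
                  names(observations)))
  ## protein attribution comes from matching; drop any incoming column
  observations <- observations[setdiff(names(observations), "protein")]
  sets <- lapply(proteins, observable_peptides, mz_range = mz_range,
                 charges = charges)
  owner <- stack(setNames(lapply(sets, unique), names(sets)))
  names(owner) <- c("peptide", "protein")
  owner$peptide <- as.character(owner$peptide)
  owner$protein <- as.character(owner$protein)
  shared_tab <- table(owner$peptide)
  m <- merge(observations, owner, by = "peptide")
  if (nrow(m)) {
    m$shared <- as.integer(shared_tab[m$peptide]) > 1L
    m <- m[order(m$region, m$protein, m$peptide),
           c("region", "protein", "peptide", "count", "shared")]
  } else {
    m <- data.frame(region = character(0), protein = character(0),
                    peptide = character(0), count = integer(0),
                    shared = logical(0))
  }
  unmatched <- sort(setdiff(unique(observations$peptide),
                            owner$peptide))
  list(matched = m, unmatched = unmatched, observable_sets = sets)
}

#' Per-region emPAI table
#'
#' @param matched result of [match_observations()] (or its `matched`
#'   data.frame plus `observable_sets`).
#' @param proteins named character vector (defines the full protein set,
#'   including proteins with zero observations).
#' @param regions regions to report; defaults to the regions present in
#'   the matched observations. Regions without observations report
#'   emPAI 0 for every protein.
#' @inheritParams observable_peptides
#' @return data.frame of emPAI records: region, protein, n_observed,
#'   n_observable, empai.
#' @export
empai_table <- function(matched, proteins, regions = NULL,
                        mz_range = c(400, 1500), charges = c(2L, 3L)) {
  if (!is.list(matched) || is.data.frame(matched))
    stop("pass the result of match_observations()")
  sets <- matched$observable_sets
  m <- matched$matched
  if (is.null(regions)) regions <- unique(m$region)
  if (!length(regions)) regions <- "all"
  rows <- list()
  for (rg in regions) {
    for (pn in names(proteins)) {
      n_able <- length(unique(sets[[pn]]))
      peps <- unique(m$peptide[m$region == rg & m$protein == pn])
      n_obs <- length(peps)
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, protein = pn, n_observed = n_obs,
        n_observable = n_able,
        empai = if (n_able >= 1L) empai(n_obs, n_able) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Region comparison report
#'
#' Per region and protein: emPAI, within-region rank, and pairwise
#' region ratios; when a `replicate` column is present in the matched
#' observations, a Wilcoxon rank-sum test compares per-replicate emPAI
#' between each pair of regions for each protein.
#'
#' @param records emPAI records from [empai_table()].
#' @param matched optional [match_observations()] result with a
#'   `replicate` column in its observations for significance testing.
#' @param proteins named protein vector (needed for per-replicate
#'   emPAI when testing).
#' @return list: `records` (with `rank` added), `ratios` (long
#'   data.frame protein/region_a/region_b/ratio), `tests` (or NULL).
#' @export
region_report <- function(records, matched = NULL, proteins = NULL) {
  records <- do.call(rbind, lapply(split(records, records$region),
    function(d) {
      d$rank <- rank(-d$empai, ties.method = "min")
      d
    }))
  rownames(records) <- NULL
  regions <- unique(records$region)
  ratios <- list()
  if (length(regions) > 1L) {
    for (a in regions) for (b in regions) {
      if (a >= b) next
      da <- records[records$region == a, ]
      db <- records[records$region == b, ]
      common <- intersect(da$protein, db$protein)
      ratios[[length(ratios) + 1L]] <- data.frame(
        protein = common, region_a = a, region_b = b,
        ratio = da$empai[match(common, da$protein)] /
          pmax(db$empai[match(common, db$protein)], 1e-9))
    }
  }
  ratios <- if (length(ratios)) do.call(rbind, ratios) else NULL
  tests <- NULL
  if (!is.null(matched) && !is.null(proteins) &&
      "replicate" %in% names(matched$matched)) {
    m <- matched$matched
    sets <- matched$observable_sets
    per_rep <- aggregate(
      list(n_observed = m$peptide),
      by = list(region = m$region, protein = m$protein,
                replicate = m$replicate),
      FUN = function(p) length(unique(p)))
    per_rep$empai <- empai(per_rep$n_observed,
                           vapply(per_rep$protein, function(pn)
                             length(unique(sets[[pn]])), numeric(1)))
    tests <- list()
    for (pn in unique(per_rep$protein)) {
      d <- per_rep[per_rep$protein == pn, ]
      regs <- unique(d$region)
      for (a in regs) for (b in regs) {
        if (a >= b) next
        xa <- d$empai[d$region == a]; xb <- d$empai[d$region == b]
        if (length(xa) > 1L && length(xb) > 1L) {
          wt <- suppressWarnings(wilcox.test(xa, xb))
          tests[[length(tests) + 1L]] <- data.frame(
            protein = pn, region_a = a, region_b = b,
            p_value = wt$p.value)
        }
      }
    }
    tests <- if (length(tests)) do.call(rbind, tests) else NULL
  }
  list(records = records, ratios = ratios, tests = tests)
}
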