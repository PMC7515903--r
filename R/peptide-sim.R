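## Simulated peptide observations across web regions, with
## region-biased protein abundance and saturating detection.

#' Peptide observation model
#'
#' Per-region relative protein abundances with a saturating detection
#' probability `p = a / (a + detect_k)`, which is in `[0, 1]` and
#' monotone non-decreasing in abundance `a`.
#'
#' @param abundance numeric matrix: rows = proteins (named), columns =
#'   regions (named; conventionally whole_web, radius_spiral,
#'   stabilimentum).
#' @param detect_k half-saturation constant of the detection curve.
#' @param count_lambda Poisson rate for spectral counts beyond the first
#'   identification.
#' @param rng_seed integer seed.
#' @return object of class `peptide_observation_model`.
#' @export
peptide_observation_model <- function(abundance, detect_k = 1,
                                      count_lambda = 2,
                                      rng_seed = 1L) {
  stopifnot(is.matrix(abundance), !is.null(rownames(abundance)),
            !is.null(colnames(abundance)), all(abundance >= 0))
  structure(list(abundance = abundance, detect_k = detect_k,
                 count_lambda = count_lambda,
                 rng_seed = as.integer(rng_seed)),
            class = "peptide_observation_model")
}

#' Detection probability of the observation model
#' @param model a [peptide_observation_model()].
#' @param abundance numeric abundance(s).
#' @return probability in `[0, 1]`.
#' @export
detection_probability <- function(model, abundance) {
  abundance / (abundance + model$detect_k)
}

#' Simulate peptide observations per web region
#'
#' For every region and protein, each peptide of the protein's
#' observable set (digestion and observability rules of the proteomics
#' module) is detected independently with the saturating probability;
#' detected peptides get a spectral count of `1 + Poisson(count_lambda)`.
#' Only observable peptides can ever be emitted.
#'
#' @param proteins named character vector of protein sequences; names
#'   must match `rownames(model$abundance)`.
#' @param model a [peptide_observation_model()].
#' @param n_replicates optional replicate runs (adds a `replicate`
#'   column).
#' @param path optional TSV output.
#' @inheritParams observable_peptides
#' @return data.frame (region, protein, peptide, count[, replicate]).
#' @export
simulate_peptide_observations <- function(proteins, model,
                                          n_replicates = 1L,
                                          path = NULL,
                                          mz_range = c(400, 1500),
                                          charges = c(2L, 3L)) {
  stopifnot(inherits(model, "peptide_observation_model"))
  miss <- setdiff(rownames(model$abundance), names(proteins))
  if (length(miss)) stop("abundance rows without sequences: ",
                         paste(miss, collapse = ", "))
  sets <- lapply(proteins, observable_peptides, mz_range = mz_range,
                 charges = charges)
  with_seed(model$rng_seed, {
    rows <- list()
    for (rep_i in seq_len(n_replicates)) {
      for (rg in colnames(model$abundance)) {
        for (pn in rownames(model$abundance)) {
          a <- model$abundance[pn, rg]
          if (a <= 0) next
          peps <- unique(sets[[pn]])
          if (!length(peps)) next
          p <- detection_probability(model, a)
          hit <- runif(length(peps)) < p
          if (!any(hit)) next
          rows[[length(rows) + 1L]] <- data.frame(
            region = rg, protein = pn, peptide = peps[hit],
            count = 1L + rpois(sum(hit), model$count_lambda),
            replicate = rep_i)
        }
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(region = character(0), protein = character(0),
                 peptide = character(0), count = integer(0),
                 replicate = integer(0))
    if (n_replicates == 1L) out$replicate <- NULL
    if (!is.null(path))
      write.table(out, path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    out
  })
}
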