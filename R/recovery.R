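## Parameter-recovery experiment: the package's own validation loop.
## Synthetic genes spanning the realistic architecture range are pushed
## through read simulation and curation, and the curated unit and copy
## number are scored against ground truth.

#' Run a curation recovery experiment on synthetic genes
#'
#' For each replicate a gene is drawn with a repeat unit length and copy
#' number sampled uniformly from the given ranges, reads are simulated
#' (paired 150 nt short reads with substitution errors; indel-biased
#' long reads, a fraction spanning the full gene), terminal-only contig
#' fixtures are built, and [curate_gene()] is run. Scored per
#' replicate: rotational identity of the curated unit to truth, the
#' copy-number error, and continuity validation.
#'
#' @param n replicates.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param unit_range,copies_range sampling ranges for the repeat unit
#'   length (nt) and copy number.
#' @param per_copy_divergence substitution rate between repeat copies.
#' @param short_error,long_error read error rates.
#' @param coverage_short,coverage_long fold coverages.
#' @param families families to cycle through (terminal-domain lengths
#'   and motif vocabularies come from the family defaults).
#' @param k,min_depth,min_purity curation parameters.
#' @param verbose print one line per replicate.
#' @return data.frame: replicate, family, unit_len, n_copies,
#'   unit_identity, est_copies, copy_error, continuity, elapsed_s.
#' @export
recovery_experiment <- function(n = 20L, seed = 1L,
                                unit_range = c(200L, 1200L),
                                copies_range = c(5L, 15L),
                                per_copy_divergence = 0.01,
                                short_error = 0.001, long_error = 0.10,
                                coverage_short = 30, coverage_long = 20,
                                families = c("MaSp", "MiSp", "AcSp",
                                             "CySp", "PySp", "AgSp",
                                             "CrSp", "Pflag", "Flag"),
                                k = 72L, min_depth = 5L,
                                min_purity = 0.8, verbose = FALSE) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rseed <- (as.integer(seed) * 1009L + i * 9973L) %% 2147483000L
    prm <- with_seed(rseed, list(
      unit_len = sample(seq.int(unit_range[1L], unit_range[2L]), 1L),
      n_copies = sample(seq.int(copies_range[1L], copies_range[2L]), 1L),
      family = families[(i - 1L) %% length(families) + 1L]))
    t0 <- Sys.time()
    model <- spidroin_gene_model(prm$family, unit_len = prm$unit_len,
                                 n_copies = prm$n_copies,
                                 per_copy_divergence = per_copy_divergence,
                                 seed = rseed + 1L)
    g <- generate_gene(model, seed = rseed + 2L,
                       gene_id = sprintf("rec%02d_%s", i, prm$family))
    cfg <- read_sim_config(short_error_rate = short_error,
                           long_error_rate = long_error,
                           coverage_short = coverage_short,
                           coverage_long = coverage_long,
                           insert_mean = 350, insert_sd = 35,
                           long_len_mean = nchar(g$cds) + 800L,
                           span_fraction = 0.6, rng_seed = rseed + 3L)
    ref <- flanked_reference(g, flank = 400L, seed = rseed + 4L)
    refs <- setNames(ref$ref, g$gene_id)
    sr <- simulate_short_reads(refs, cfg)
    lr <- simulate_long_reads(refs, cfg)
    contigs <- make_contig_fixtures(g, "terminal_only")
    res <- tryCatch(
      curate_gene(contigs, c(sr$r1, sr$r2), lr$reads,
                  profiles_from_genes(g), gene_id = g$gene_id,
                  k = k, min_depth = min_depth,
                  min_purity = min_purity),
      error = function(e) e)
    el <- as.numeric(Sys.time() - t0, units = "secs")
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(
        replicate = i, family = prm$family, unit_len = prm$unit_len,
        n_copies = prm$n_copies, unit_identity = 0,
        est_copies = NA_integer_, copy_error = NA_integer_,
        continuity = FALSE, error = conditionMessage(res),
        elapsed_s = el)
    } else {
      rows[[i]] <- data.frame(
        replicate = i, family = prm$family, unit_len = prm$unit_len,
        n_copies = prm$n_copies,
        unit_identity = rotational_identity(res$repeat_unit_nt,
                                            g$repeat_unit_nt),
        est_copies = res$n_copies_estimate,
        copy_error = res$n_copies_estimate - prm$n_copies,
        continuity = res$continuity_validated,
        error = NA_character_, elapsed_s = el)
    }
    if (verbose)
      message(sprintf(
        "rep %02d %-5s unit %4d x %2d -> id %.4f, copies %s (%.1fs)",
        i, prm$family, prm$unit_len, prm$n_copies,
        rows[[i]]$unit_identity,
        if (is.na(rows[[i]]$est_copies)) "fail" else rows[[i]]$est_copies,
        el))
  }
  do.call(rbind, rows)
}
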