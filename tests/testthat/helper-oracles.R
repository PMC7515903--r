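# Independent brute-force oracles used to validate the package
# implementations on small inputs. These are written from the operation
# definitions, not from the package code paths.

# All-period tandem scan: smallest p whose trailing window (3p, at
# least 2p available) self-aligns at >= id_threshold, character loops
# only.
oracle_detect_period <- function(sequence, min_period = 1L,
                                 id_threshold = 0.9, window_mult = 3) {
  x <- strsplit(sequence, "")[[1]]
  n <- length(x)
  self_id <- function(w, p) {
    tail_x <- x[(n - w + 1):n]
    mean(tail_x[1:(w - p)] == tail_x[(p + 1):w])
  }
  for (p in seq_len(n %/% 2)) {
    if (p < min_period) next
    # accept on the full window or on the minimal two-copy window
    for (w in unique(c(min(round(window_mult * p), n), 2 * p))) {
      if (w < 2 * p || w > n) next
      if (self_id(w, p) >= id_threshold) return(p)
    }
  }
  NULL
}

# Brute-force digestion: find cleavage sites by direct rule scan, then
# enumerate every fragment run with <= max_missed internal sites.
oracle_digest <- function(protein, max_missed = 2L) {
  x <- strsplit(protein, "")[[1]]
  n <- length(x)
  sites <- integer(0)
  for (i in seq_len(n - 1)) {
    if ((x[i] == "K" || x[i] == "R") && x[i + 1] != "P")
      sites <- c(sites, i)
  }
  bounds <- c(0L, sites, n)
  peps <- character(0)
  missed <- integer(0)
  nf <- length(bounds) - 1L
  for (i in seq_len(nf)) {
    for (j in i:min(nf, i + max_missed)) {
      peps <- c(peps, substr(protein, bounds[i] + 1L, bounds[j + 1L]))
      missed <- c(missed, j - i)
    }
  }
  data.frame(peptide = peps, missed = missed)
}

# Leftmost greedy parse of glycine motifs with longer-motif precedence,
# implemented recursively (position-by-position) rather than with the
# package's consumed-mask scanner.
oracle_g_motifs <- function(aa) {
  x <- strsplit(aa, "")[[1]]
  counts <- c(GPGGX = 0L, GPSS = 0L, GGX = 0L)
  i <- 1L
  n <- length(x)
  while (i <= n) {
    took <- 0L
    if (i + 4 <= n && all(x[i:(i + 3)] == c("G", "P", "G", "G"))) {
      counts["GPGGX"] <- counts["GPGGX"] + 1L; took <- 5L
    } else if (i + 3 <= n &&
               all(x[i:(i + 3)] == c("G", "P", "S", "S"))) {
      counts["GPSS"] <- counts["GPSS"] + 1L; took <- 4L
    } else if (i + 2 <= n && x[i] == "G" && x[i + 1] == "G") {
      counts["GGX"] <- counts["GGX"] + 1L; took <- 3L
    }
    i <- i + max(took, 1L)
  }
  counts
}

# random DNA / protein helpers
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
rand_aa <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                           "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a small zero/low-error curation scenario shared by smoc tests
make_curation_scenario <- function(family = "Pflag", unit_len = 300L,
                                   n_copies = 5L, divergence = 0,
                                   short_error = 0, long_error = 0,
                                   seed = 11L) {
  model <- spidroin_gene_model(family, unit_len = unit_len,
                               n_copies = n_copies,
                               per_copy_divergence = divergence,
                               seed = seed)
  g <- generate_gene(model, seed = seed + 1L)
  cfg <- read_sim_config(short_error_rate = short_error,
                         long_error_rate = long_error,
                         insert_mean = 350, insert_sd = 35,
                         long_len_mean = nchar(g$cds) + 800L,
                         span_fraction = 0.6, rng_seed = seed + 2L)
  ref <- flanked_reference(g, 400L, seed = seed + 3L)
  refs <- setNames(ref$ref, g$gene_id)
  sr <- simulate_short_reads(refs, cfg)
  lr <- simulate_long_reads(refs, cfg)
  list(gene = g, cfg = cfg, refs = refs, short = c(sr$r1, sr$r2),
       long = lr$reads,
       contigs = make_contig_fixtures(g, "terminal_only"),
       profiles = profiles_from_genes(g))
}
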