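test_that("gene models assemble to the expected architecture", {
  m <- spidroin_gene_model("CrSp", unit_len = 1009, ctd_len = 962,
                           n_copies = 11, per_copy_divergence = 0,
                           seed = 1)
  g <- generate_gene(m, seed = 2)
  expect_equal(nchar(g$cds), nchar(m$ntd_nt) + 11 * 1009 + 962)
  expect_equal(g$truth$end[3] - g$truth$start[1], nchar(g$cds))
  # truth-table slices reproduce the stored domain sequences
  tr <- g$truth
  expect_equal(substr(g$cds, tr$start[1] + 1, tr$end[1]), g$ntd_nt)
  expect_equal(substr(g$cds, tr$start[3] + 1, tr$end[3]), g$ctd_nt)
  # zero divergence: all copies identical to the unit
  expect_true(all(g$copies == m$repeat_unit_nt))
})

test_that("gene generation is deterministic and rejects bad input", {
  m <- spidroin_gene_model("MaSp", seed = 5)
  g1 <- generate_gene(m, seed = 9)
  g2 <- generate_gene(m, seed = 9)
  expect_identical(g1$cds, g2$cds)
  expect_error(spidroin_gene_model("MaSp", n_copies = 1),
               "n_copies")
  expect_error(spidroin_gene_model("MaSp", motifs = c("GGA", "MCW")),
               "stop-encoding")
  expect_error(spidroin_gene_model("MaSp", per_copy_divergence = 0.5),
               "per_copy_divergence")
})

test_that("translated frame stays open for any unit length", {
  for (seed in 1:5) {
    ul <- sample(c(200, 301, 503, 1009, 1124), 1)
    m <- spidroin_gene_model(sample(c("CrSp", "Pflag", "Flag"), 1),
                             unit_len = ul,
                             n_copies = sample(2:12, 1),
                             per_copy_divergence = 0.05, seed = seed)
    g <- generate_gene(m, seed = seed + 100)
    body <- substr(g$protein, 1, nchar(g$protein) - 1)
    expect_false(grepl("*", body, fixed = TRUE),
                 info = paste("seed", seed, "unit", ul))
  }
})

test_that("short-read simulation respects coverage and error model", {
  set.seed(1)
  ref <- c(chr = rand_dna(10000))
  cfg <- read_sim_config(short_error_rate = 0, coverage_short = 30,
                         rng_seed = 3)
  sim <- simulate_short_reads(ref, cfg)
  reads <- c(sim$r1, sim$r2)
  # realized coverage within 10% of requested
  fold <- sum(nchar(reads)) / nchar(ref)
  expect_gte(fold, 27)
  expect_lte(fold, 33)
  # zero error: every read is an exact substring of the reference
  rc <- revcomp(ref)
  hit <- vapply(reads, function(r)
    grepl(r, ref, fixed = TRUE) || grepl(r, rc, fixed = TRUE),
    logical(1))
  expect_true(all(hit))
  expect_equal(nrow(sim$log), 0)
  # mate naming
  expect_true(all(grepl("/1$", names(sim$r1))))
  expect_true(all(grepl("/2$", names(sim$r2))))
  expect_error(simulate_short_reads(character(0), cfg), "no reference")
})

test_that("read simulation is byte-identical under a fixed seed", {
  ref <- c(chr = rand_dna(8000))
  cfg <- read_sim_config(rng_seed = 77)
  d <- withr::local_tempdir()
  a <- simulate_short_reads(ref, cfg, prefix = file.path(d, "a"))
  b <- simulate_short_reads(ref, cfg, prefix = file.path(d, "b"))
  expect_identical(unname(tools::md5sum(a$r1_path)),
                   unname(tools::md5sum(b$r1_path)))
  la <- simulate_long_reads(ref, cfg, prefix = file.path(d, "la"))
  lb <- simulate_long_reads(ref, cfg, prefix = file.path(d, "lb"))
  expect_identical(unname(tools::md5sum(la$path)),
                   unname(tools::md5sum(lb$path)))
})

test_that("long-read simulation: spans, indel bias, error logs", {
  ref <- c(g = rand_dna(9000))
  cfg0 <- read_sim_config(long_error_rate = 0, span_fraction = 1,
                          rng_seed = 5)
  sim0 <- simulate_long_reads(ref, cfg0)
  spans <- sim0$reads[grepl("_span$", names(sim0$reads))]
  expect_gt(length(spans), 0)
  # zero error + spanning: reads equal the reference (either strand)
  expect_true(all(spans == ref | spans == revcomp(ref)))

  cfg <- read_sim_config(long_error_rate = 0.10, indel_bias = 0.8,
                         rng_seed = 6)
  sim <- simulate_long_reads(ref, cfg)
  indel_frac <- mean(sim$log$type != "sub")
  expect_gte(indel_frac, 0.7)
  # realized error rate near nominal (exact audit via the log)
  expect_equal(nrow(sim$log) / sum(nchar(sim$reads)), 0.10,
               tolerance = 0.15)
})

test_that("contig fixtures mimic assembler truncation policies", {
  g <- generate_gene(spidroin_gene_model("Flag", seed = 2), seed = 3)
  expect_identical(unname(make_contig_fixtures(g, "perfect")), g$cds)
  col <- make_contig_fixtures(g, "repeat_collapse")
  expect_equal(nchar(col[[1]]),
               nchar(g$ntd_nt) + 2 * nchar(g$repeat_unit_nt) +
                 nchar(g$ctd_nt))
  ter <- make_contig_fixtures(g, "terminal_only")
  expect_named(ter, c(paste0(g$gene_id, "_NTD"),
                      paste0(g$gene_id, "_CTD")))
  expect_identical(unname(ter[1]), g$ntd_nt)
})

test_that("peptide observation simulation honours the detection model", {
  g1 <- generate_gene(spidroin_gene_model("MaSp", seed = 4), seed = 5)
  g2 <- generate_gene(spidroin_gene_model("AcSp", seed = 6), seed = 7)
  prots <- c(MaSp = gsub("\\*", "", g1$protein),
             AcSp = gsub("\\*", "", g2$protein))
  ab <- matrix(c(1, 0,
                 1, 10), nrow = 2, byrow = TRUE,
               dimnames = list(c("MaSp", "AcSp"),
                               c("radius_spiral", "stabilimentum")))
  ab["MaSp", "stabilimentum"] <- 1
  ab["MaSp", "radius_spiral"] <- 1
  ab["AcSp", "radius_spiral"] <- 1
  # zero abundance emits nothing
  ab0 <- ab; ab0["MaSp", ] <- 0
  m0 <- peptide_observation_model(ab0, rng_seed = 8)
  obs0 <- simulate_peptide_observations(prots, m0)
  expect_false("MaSp" %in% obs0$protein)
  # detect_k = 0 makes detection certain: observed set = observable set
  m1 <- peptide_observation_model(ab, detect_k = 0, rng_seed = 9)
  obs1 <- simulate_peptide_observations(prots, m1)
  got <- sort(unique(obs1$peptide[obs1$protein == "MaSp" &
                                    obs1$region == "stabilimentum"]))
  expect_identical(got, sort(unique(observable_peptides(prots["MaSp"]))))
  # detection probability is bounded and monotone
  mm <- peptide_observation_model(ab, detect_k = 2)
  p <- detection_probability(mm, c(0, 0.5, 1, 5, 100))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) > 0))
  # enrichment: 10x AcSp in stabilimentum gives strictly more distinct
  # AcSp peptides there (detection prob < 1, fixed seed)
  m2 <- peptide_observation_model(ab, detect_k = 5, rng_seed = 10)
  obs2 <- simulate_peptide_observations(prots, m2)
  n_stab <- length(unique(obs2$peptide[obs2$protein == "AcSp" &
                                         obs2$region == "stabilimentum"]))
  n_rad <- length(unique(obs2$peptide[obs2$protein == "AcSp" &
                                        obs2$region == "radius_spiral"]))
  expect_gt(n_stab, n_rad)
})
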