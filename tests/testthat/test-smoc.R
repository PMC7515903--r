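test_that("k-mer screen indexes both strands with exact counts", {
  read <- c(r1 = strrep("ACGT", 40))  # 160 nt
  idx <- build_kmer_screen(read, k = 100)
  expect_equal(sum(idx$table$strand == "+"), 61)
  expect_equal(sum(idx$table$strand == "-"), 61)
  expect_error(build_kmer_screen(read, k = 200), "exceeds")
  # duplicate reads preserve multiplicity
  set.seed(42)
  r <- rand_dna(150)
  idx2 <- build_kmer_screen(c(a = r, b = r), k = 100)
  km <- substr(r, 1, 100)
  expect_equal(nrow(recruit_and_align(km, idx2)$hits), 2)
})

test_that("recruitment aligns 3' overhangs gap-free", {
  set.seed(7)
  anchor <- rand_dna(40)
  reads <- c(x = paste0(anchor, "AAG"), y = paste0(anchor, "AAG"),
             z = paste0(anchor, "AAT"), w = anchor)  # w: zero overhang
  idx <- build_kmer_screen(reads, k = 40)
  rec <- recruit_and_align(anchor, idx)
  expect_equal(length(rec$overhangs), 4)
  pw <- pwm_from_overhangs(rec$overhangs)
  expect_equal(unname(pw$counts["G", 3]), 2)
  expect_equal(unname(pw$counts["T", 3]), 1)
  expect_equal(pw$support[1], 3)  # zero-overhang read adds no columns
  # absent k-mer recruits nothing
  expect_equal(length(recruit_and_align(strrep("A", 40), idx)$overhangs),
               0)
  expect_error(recruit_and_align("ACGT", idx), "index k")
})

test_that("PWM conservation invariant holds on random overhang sets", {
  set.seed(11)
  for (rep in 1:5) {
    ov <- vapply(sample(0:30, 12, replace = TRUE), rand_dna,
                 character(1))
    pw <- pwm_from_overhangs(ov)
    if (ncol(pw$counts) == 0) next
    for (j in seq_len(ncol(pw$counts))) {
      expect_equal(sum(pw$counts[, j]), sum(nchar(ov) >= j))
      # consensus base is the argmax of its column
      expect_equal(substr(pw$consensus, j, j),
                   rownames(pw$counts)[which.max(pw$counts[, j])])
    }
  }
})

test_that("repeat unit detection finds the smallest qualifying period", {
  r <- detect_repeat_unit("ACGACGACGACG")
  expect_equal(r$period, 3)
  expect_equal(r$unit, "ACG")
  # planted unit after a unique prefix
  set.seed(13)
  unit <- rand_dna(300)
  seq1 <- paste0(rand_dna(500), strrep(unit, 4))
  r1 <- detect_repeat_unit(seq1, min_period = 10)
  expect_equal(r1$period, 300)
  expect_equal(r1$unit, unit)
  # aperiodic sequence yields nothing
  expect_null(detect_repeat_unit(rand_dna(1000), min_period = 10))
})

test_that("repeat detection agrees with the all-period oracle", {
  set.seed(17)
  for (i in 1:40) {
    if (i %% 2 == 0) {
      u <- rand_dna(sample(20:300, 1))
      s <- paste0(rand_dna(sample(0:400, 1)),
                  strrep(u, sample(2:5, 1)))
    } else {
      s <- rand_dna(sample(200:2000, 1))
    }
    got <- detect_repeat_unit(s, min_period = 5)
    want <- oracle_detect_period(s, min_period = 5)
    if (is.null(want)) expect_null(got, info = paste("case", i))
    else expect_equal(got$period, want, info = paste("case", i))
  }
})

test_that("extension walks from the NTD into the repeat and stops", {
  sc <- make_curation_scenario(unit_len = 300, n_copies = 5,
                               divergence = 0, short_error = 0)
  idx <- build_kmer_screen(sc$short, k = 72)
  ext <- extend_consensus(sc$gene$ntd_nt, idx)
  expect_equal(ext$stop_reason, "repeat_detected")
  truth_prefix <- substr(sc$gene$cds, 1, nchar(ext$consensus))
  expect_equal(ext$consensus, truth_prefix)  # 100% identity
  expect_gte(nrow(ext$steps), 1)
  # a low-error run reproduces the zero-error consensus
  sc2 <- make_curation_scenario(unit_len = 300, n_copies = 5,
                                divergence = 0, short_error = 0.001)
  idx2 <- build_kmer_screen(sc2$short, k = 72)
  ext2 <- extend_consensus(sc2$gene$ntd_nt, idx2)
  n <- min(nchar(ext$consensus), nchar(ext2$consensus))
  expect_equal(substr(ext2$consensus, 1, n), substr(ext$consensus, 1, n))
  # impossible depth: immediate stop, no extension
  ext3 <- extend_consensus(sc$gene$ntd_nt, idx, min_depth = 1000)
  expect_equal(nchar(ext3$consensus), nchar(sc$gene$ntd_nt))
  expect_equal(ext3$stop_reason, "support_exhausted")
})

test_that("iteration counting from long reads recovers copy number", {
  m <- spidroin_gene_model("Flag", unit_len = 300, n_copies = 11,
                           per_copy_divergence = 0, seed = 21)
  g <- generate_gene(m, seed = 22)
  # one error-free spanning read
  est <- estimate_iterations(g$ntd_nt, g$repeat_unit_nt, g$ctd_nt,
                             c(lr1 = g$cds))
  expect_equal(est$n_copies_estimate, 11)
  expect_true(est$continuity_validated)
  expect_equal(est$spanning_read_ids, "lr1")
  # reads from an unrelated gene: no span, low confidence
  other <- generate_gene(spidroin_gene_model("MaSp", seed = 23),
                         seed = 24)
  est2 <- estimate_iterations(g$ntd_nt, g$repeat_unit_nt, g$ctd_nt,
                              c(lr1 = other$cds))
  expect_false(est2$continuity_validated)
  expect_true(est2$low_confidence)
  # noisy long reads, ~10% indel-biased error: within +/- 1
  sc <- make_curation_scenario(family = "Flag", unit_len = 300,
                               n_copies = 12, divergence = 0.01,
                               short_error = 0.001, long_error = 0.10,
                               seed = 31)
  est3 <- estimate_iterations(sc$gene$ntd_nt, sc$gene$repeat_unit_nt,
                              sc$gene$ctd_nt, sc$long)
  expect_lte(abs(est3$n_copies_estimate - 12), 1)
})

test_that("seed discovery hits true terminals and keeps FPR low", {
  g <- generate_gene(spidroin_gene_model("Pflag", seed = 41), seed = 42)
  prof <- profiles_from_genes(g)
  contigs <- make_contig_fixtures(g, "terminal_only")
  hits <- find_seeds(contigs, prof)
  expect_setequal(unique(hits$category), c("NTD", "CTD"))
  nh <- hits[hits$category == "NTD", ][1, ]
  expect_equal(c(nh$start, nh$end), c(1, nchar(g$ntd_nt)))
  # reverse-complemented contig: same hit, strand flagged
  rc_hits <- find_seeds(c(rc = revcomp(contigs[[1]])), prof)
  nh_rc <- rc_hits[rc_hits$category == "NTD", ][1, ]
  expect_equal(nh_rc$strand, "-")
  expect_equal(c(nh_rc$start, nh_rc$end), c(1, nchar(g$ntd_nt)))
  # random contigs: empirical false-positive rate under 1%
  set.seed(43)
  rnd <- setNames(vapply(1:120, function(i) rand_dna(2000),
                         character(1)), paste0("rnd", 1:120))
  fp <- find_seeds(rnd, prof)
  expect_lt(nrow(fp) / length(rnd), 0.01)
  expect_error(find_seeds(contigs, prof[0, ]), "no query profiles")
})

test_that("curation assembles a complete record on clean data", {
  sc <- make_curation_scenario(unit_len = 240, n_copies = 7,
                               divergence = 0.01,
                               short_error = 0.001, long_error = 0.10,
                               seed = 51)
  cur <- curate_gene(sc$contigs, sc$short, sc$long, sc$profiles,
                     gene_id = sc$gene$gene_id)
  expect_s3_class(cur, "curated_gene")
  expect_equal(cur$ntd_flag, "complete")
  expect_equal(cur$ctd_flag, "complete")
  expect_gte(rotational_identity(cur$repeat_unit_nt,
                                 sc$gene$repeat_unit_nt), 0.99)
  expect_lte(abs(cur$n_copies_estimate - 7), 1)
  expect_true(cur$continuity_validated)
  # determinism: identical inputs give identical records
  cur2 <- curate_gene(sc$contigs, sc$short, sc$long, sc$profiles,
                      gene_id = sc$gene$gene_id)
  expect_identical(cur[c("ntd_nt", "ctd_nt", "repeat_unit_nt",
                         "n_copies_estimate")],
                   cur2[c("ntd_nt", "ctd_nt", "repeat_unit_nt",
                          "n_copies_estimate")])
  # absent CTD contig: record flagged partial
  cur3 <- curate_gene(sc$contigs[1], sc$short, sc$long, sc$profiles,
                      gene_id = sc$gene$gene_id)
  expect_equal(cur3$ctd_flag, "partial")
})

test_that("conflicting units from the two extension sides are refused", {
  # chimeric locus: the array behind the NTD differs from the array
  # before the CTD
  m <- spidroin_gene_model("CySp", unit_len = 210, n_copies = 4,
                           per_copy_divergence = 0, seed = 61)
  m2 <- spidroin_gene_model("PySp", unit_len = 210, n_copies = 4,
                            per_copy_divergence = 0, seed = 62)
  cds <- paste0(m$ntd_nt, strrep(m$repeat_unit_nt, 4),
                strrep(m2$repeat_unit_nt, 4), m$ctd_nt)
  cfg <- read_sim_config(short_error_rate = 0, insert_mean = 350,
                         insert_sd = 35, rng_seed = 63,
                         long_len_mean = nchar(cds) + 800)
  ref <- flanked_reference(cds, 400, seed = 64)
  sr <- simulate_short_reads(c(chim = ref$ref), cfg)
  lr <- simulate_long_reads(c(chim = ref$ref), cfg)
  contigs <- c(chim_NTD = m$ntd_nt, chim_CTD = m$ctd_nt)
  prof <- data.frame(
    name = c("p_NTD", "p_CTD"), category = c("NTD", "CTD"),
    sequence = c(translate_nt(m$ntd_nt), translate_nt(m$ctd_nt)))
  expect_error(
    curate_gene(contigs, c(sr$r1, sr$r2), lr$reads, prof,
                gene_id = "chim"),
    "conflicting repeat units")
})
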