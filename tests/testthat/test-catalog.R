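test_that("Kozak context drives start-codon selection", {
  orf <- paste0(strrep("GCC", 80), "TAA")  # 80 Ala codons then stop
  good <- paste0("GCCACC", "ATG", "G", orf)
  bad <- paste0("TTTTTT", "ATG", "C", orf)
  sg <- select_start_codon(good, min_orf_aa = 50)
  sb <- select_start_codon(bad, min_orf_aa = 50)
  expect_equal(sg$position, 7)
  expect_equal(sb$position, 7)
  expect_gt(sg$score, sb$score)
  # a single qualifying ATG is returned regardless of context
  expect_equal(select_start_codon(bad, min_orf_aa = 50)$position, 7)
  expect_error(select_start_codon("GGGCCC"), "no ATG")
  expect_error(select_start_codon(paste0("ATG", strrep("GCC", 5), "TAA"),
                                  min_orf_aa = 50), "ORF")
})

test_that("equal Kozak scores are separated by the signal-peptide score", {
  # two ATGs with identical context; the second opens a hydrophobic
  # N-terminus (signal-peptide-like), the first an acidic one
  hydrophilic <- strrep("GAC", 40)                      # poly-Asp
  hydrophobic <- paste0(strrep("GTT", 25), strrep("GCT", 15))  # Val/Ala
  cdna <- paste0("AAAA", "ATG", hydrophilic,
                 "AAAA", "ATG", hydrophobic, "TAA")
  sel <- select_start_codon(cdna, min_orf_aa = 40)
  expect_equal(nrow(sel$candidates), 2)
  expect_equal(length(unique(sel$candidates$kozak)), 1)
  expect_equal(sel$position, sel$candidates$position[2])
})

test_that("signal-peptide heuristic scores hydropathy windows", {
  high <- signal_peptide_score(paste0("MK", strrep("L", 15)))
  low <- signal_peptide_score(strrep("D", 20))
  expect_gt(high, 0.7)
  expect_lt(low, 0.3)
  # invariant to sequence beyond residue 30
  base <- paste0("MK", strrep("L", 28))
  expect_equal(signal_peptide_score(base),
               signal_peptide_score(paste0(base, strrep("D", 200))))
  expect_gte(low, 0)
  expect_lte(high, 1)
})

test_that("domain segmentation recovers truth-table boundaries", {
  g <- generate_gene(spidroin_gene_model("Flag", seed = 3,
                                         per_copy_divergence = 0.01),
                     seed = 4)
  ann <- segment_domains(g$cds, profiles_from_genes(g),
                         gene_id = g$gene_id)
  tr <- g$truth
  expect_lte(abs(ann$ntd[2] - tr$end[1]), 15)
  expect_lte(abs(ann$ctd[1] - (tr$start[3] + 1)), 15)
  expect_equal(ann$n_copies, g$n_copies)
  expect_false(any(ann$partial))
  # intervals ordered and non-overlapping
  expect_true(ann$ntd[2] < ann$rtd[1] && ann$rtd[2] < ann$ctd[1])
  # re-running on the same input changes nothing (idempotent)
  ann2 <- segment_domains(g$cds, profiles_from_genes(g),
                          gene_id = g$gene_id)
  expect_identical(ann[c("ntd", "rtd", "ctd", "n_copies")],
                   ann2[c("ntd", "rtd", "ctd", "n_copies")])
  # missing CTD flags partial
  no_ctd <- substr(g$cds, 1, g$truth$end[2])
  ann3 <- segment_domains(no_ctd, profiles_from_genes(g))
  expect_true(ann3$partial["ctd"])
})

test_that("CrSp defaults reproduce the long N-terminal domain", {
  g <- generate_gene(spidroin_gene_model("CrSp", seed = 8), seed = 9)
  ann <- annotate_gene(g)
  expect_gt(ann$ntd[2] - ann$ntd[1] + 1, 2000)
  expect_equal(ann$n_copies, 11)
  expect_equal(round(ann$unit_len_mean), 1009)
})

test_that("motif scanning follows the precedence rules", {
  m1 <- scan_motifs("AAAAAGGAGGS")
  expect_equal(unname(m1["polyA"]), 1L)
  expect_equal(unname(m1["GGX"]), 2L)
  m2 <- scan_motifs("GPSSQQ")
  expect_equal(unname(m2["GPSS"]), 1L)
  expect_equal(unname(m2["QQ"]), 1L)
  expect_equal(unname(m2["SS"]), 0L)
  m3 <- scan_motifs("")
  expect_true(all(m3 == 0L))
  # GPGGX outranks GGX
  m4 <- scan_motifs("GPGGA")
  expect_equal(unname(m4["GPGGX"]), 1L)
  expect_equal(unname(m4["GGX"]), 0L)
  # dipeptide runs count floor(run/2)
  m5 <- scan_motifs("QQQQQTTT")
  expect_equal(unname(m5["QQ"]), 2L)
  expect_equal(unname(m5["TT"]), 1L)
})

test_that("glycine-motif counts match the recursive parse oracle", {
  set.seed(19)
  for (i in 1:50) {
    s <- rand_aa(sample(5:30, 1), alphabet = c("G", "P", "S", "Q",
                                               "A", "T"))
    got <- scan_motifs(s)
    want <- oracle_g_motifs(s)
    expect_equal(unname(got[c("GPGGX", "GPSS", "GGX")]),
                 unname(want), info = s)
  }
})

test_that("catalogue table aggregates per-family means", {
  genes <- make_species_set("Pflag", n_species = 3, divergence = 0.03,
                            seed = 5)
  anns <- lapply(genes$Pflag, annotate_gene)
  tab <- catalog_table(anns)
  expect_equal(nrow(tab$genes), 3)
  expect_equal(tab$family_means$unit_len_mean,
               mean(tab$genes$unit_len_mean))
  empty <- catalog_table(list())
  expect_equal(nrow(empty$genes), 0)
  d <- withr::local_tempdir()
  catalog_table(anns, path = file.path(d, "cat.tsv"))
  expect_true(file.exists(file.path(d, "cat.tsv")))
  expect_true(file.exists(file.path(d, "cat_family_means.tsv")))
})

test_that("packaged terminal profiles load and drive segmentation", {
  prof <- default_terminal_profiles()
  expect_setequal(unique(prof$category), c("NTD", "CTD"))
  expect_equal(nrow(prof), 18)
  # the CrSp profiles segment a CrSp-architecture gene
  g <- generate_gene(spidroin_gene_model("CrSp", seed = 2026L), seed = 1)
  ann <- segment_domains(g$cds, prof[grepl("^CrSp", prof$name), ])
  expect_gt(ann$ntd[2], 2000)
})
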