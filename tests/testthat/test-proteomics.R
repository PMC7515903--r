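test_that("digestion follows the trypsin rule with missed cleavages", {
  d0 <- digest("AKGRPGLK", max_missed = 0)
  expect_setequal(d0$peptide, c("AK", "GRPGLK"))  # RP blocks cleavage
  d1 <- digest("AKGRPGLK", max_missed = 1)
  expect_setequal(d1$peptide, c("AK", "GRPGLK", "AKGRPGLK"))
  # no cleavage site: the whole protein is one peptide
  expect_equal(digest("GASGASGAS")$peptide[1], "GASGASGAS")
  d3 <- digest("KKK", max_missed = 2)
  expect_setequal(unique(d3$peptide), c("K", "KK", "KKK"))
  expect_equal(nrow(d3), 6)
  expect_error(digest(""), "empty")
})

test_that("digestion equals the brute-force enumerator", {
  set.seed(61)
  for (i in 1:20) {
    p <- rand_aa(sample(10:120, 1))
    got <- digest(p, max_missed = 2)
    want <- oracle_digest(p, max_missed = 2)
    key <- function(d) sort(paste(d$peptide, d$missed))
    expect_equal(key(got), key(want), info = paste("protein", i))
  }
})

test_that("peptide masses and m/z follow the monoisotopic formulas", {
  expect_equal(peptide_mass("GG", carbamidomethyl = FALSE),
               2 * 57.02146 + 18.010565, tolerance = 1e-9)
  # fixed carbamidomethyl adds 57.02146 per Cys
  expect_equal(peptide_mass("GCG") - peptide_mass("GCG",
                                                  carbamidomethyl = FALSE),
               57.02146, tolerance = 1e-9)
  expect_equal(peptide_mz(1000, 2), (1000 + 2 * 1.007276) / 2)
  expect_true(is.na(peptide_mass("GXG")))
})

test_that("observability requires a multiply charged ion in scan range", {
  ob <- observable_filter(c("GG", "LLLLLLLLL"))
  expect_false(ob$observable[ob$peptide == "GG"])
  expect_true(ob$observable[ob$peptide == "LLLLLLLLL"])
  # a 1000 Da peptide is observable at z = 2 (m/z ~ 501)
  mass1000 <- peptide_mz(1000, 2)
  expect_gt(mass1000, 400); expect_lt(mass1000, 1500)
  expect_equal(nrow(observable_filter(character(0))), 0)
  # distinct by sequence
  ob2 <- observable_filter(c("LLLLLLLLL", "LLLLLLLLL"))
  expect_equal(nrow(ob2), 1)
})

test_that("emPAI follows its closed form and monotonicity", {
  expect_equal(empai(0, 10), 0)
  expect_equal(empai(10, 10), 9)
  expect_equal(empai(5, 10), 10^0.5 - 1, tolerance = 1e-9)
  expect_error(empai(1, 0), "n_observable")
  expect_error(empai(11, 10), "n_observed")
  for (n_able in c(3, 7, 20)) {
    vals <- empai(0:n_able, n_able)
    expect_true(all(diff(vals) > 0))
    expect_true(all(vals >= 0 & vals <= 9))
  }
})

test_that("observation matching uses distinct-sequence set semantics", {
  unit <- "GASLLNQERAALLDK"
  p2 <- paste0(strrep(unit, 2), "R")
  p11 <- paste0(strrep(unit, 11), "R")
  prots <- c(two = p2, eleven = p11)
  # identical observable sets despite different copy numbers
  expect_setequal(observable_peptides(p2), observable_peptides(p11))
  obs <- data.frame(region = "w", peptide = observable_peptides(p2)[1],
                    count = 3)
  mm <- match_observations(obs, prots)
  # the repeat peptide matches both proteins, flagged shared
  expect_setequal(mm$matched$protein, c("two", "eleven"))
  expect_true(all(mm$matched$shared))
  et <- empai_table(mm, prots)
  expect_equal(et$empai[et$protein == "two"],
               et$empai[et$protein == "eleven"])
  # unmatched peptides are reported
  obs2 <- rbind(obs, data.frame(region = "w", peptide = "WWWWWWWW",
                                count = 1))
  expect_equal(match_observations(obs2, prots)$unmatched, "WWWWWWWW")
})

test_that("region report ranks emPAI and handles empty regions", {
  set.seed(67)
  prots <- setNames(vapply(1:3, function(i)
    rand_aa(400, alphabet = strsplit("ACDEFGHIKLNPQSTV", "")[[1]]),
    character(1)), c("MaSp", "AcSp", "Pflag"))
  ab <- matrix(2, nrow = 3, ncol = 2,
               dimnames = list(names(prots),
                               c("radius_spiral", "stabilimentum")))
  ab["AcSp", "stabilimentum"] <- 40
  ab["AcSp", "radius_spiral"] <- 0.5
  mod <- peptide_observation_model(ab, detect_k = 3, rng_seed = 71)
  obs <- simulate_peptide_observations(prots, mod)
  mm <- match_observations(obs, prots)
  et <- empai_table(mm, prots)
  rep <- region_report(et)
  stab <- rep$records[rep$records$region == "stabilimentum", ]
  expect_equal(stab$rank[stab$protein == "AcSp"], 1)
  # a region with zero observations reports emPAI 0 throughout
  et0 <- empai_table(mm, prots, regions = c("stabilimentum", "empty"))
  expect_true(all(et0$empai[et0$region == "empty"] == 0))
})
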