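test_that("terminal trimming keeps 90 N / 80 C residues", {
  set.seed(31)
  p <- c(long = rand_aa(300), short = rand_aa(60))
  tn <- trim_terminals(p, end = "N")
  expect_equal(nchar(tn$sequence), c(90, 60))
  expect_equal(tn$sequence[1], substr(p[["long"]], 1, 90))
  expect_equal(tn$short, c(FALSE, TRUE))
  tc <- trim_terminals(p, end = "C")
  expect_equal(tc$sequence[1], substr(p[["long"]], 221, 300))
  expect_equal(nchar(tc$sequence[2]), 60)
  expect_error(trim_terminals(c(a = "")), "empty")
})

test_that("alignment contract: equal widths, ungapping restores input", {
  set.seed(37)
  base <- rand_aa(60)
  one <- align_terminals(c(a = base))
  expect_identical(one, c(a = base))
  same <- align_terminals(c(a = base, b = base, c = base))
  expect_true(all(nchar(same) == nchar(base)))
  expect_false(any(grepl("-", same, fixed = TRUE)))
  # one internal deletion produces exactly one gap column
  del <- paste0(substr(base, 1, 29), substr(base, 31, 60))
  aln <- align_terminals(c(a = base, b = del))
  expect_equal(length(unique(nchar(aln))), 1)
  expect_equal(sum(strsplit(aln[["b"]], "")[[1]] == "-"), 1)
  expect_identical(gsub("-", "", aln[["b"]]), del)
  expect_identical(gsub("-", "", aln[["a"]]), base)
})

test_that("distances follow the Poisson-corrected mismatch model", {
  set.seed(41)
  s <- rand_aa(100)
  x <- strsplit(s, "")[[1]]
  pos <- sample(100, 10)
  y <- x
  y[pos] <- vapply(x[pos], function(a)
    sample(setdiff(LETTERS[1:20], a), 1), character(1))
  msa <- c(a = s, b = paste(y, collapse = ""))
  D <- distance_matrix(msa)
  expect_equal(D["a", "a"], 0)
  expect_equal(D["a", "b"], -log(1 - 0.1), tolerance = 1e-9)
  expect_equal(D, t(D))
  # saturation is capped
  msa2 <- c(a = strrep("A", 50), b = strrep("W", 50))
  expect_equal(distance_matrix(msa2, max_dist = 5)["a", "b"], 5)
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(43)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.4))
    tr <- ape::unroot(tr)
    D <- cophenetic(tr)
    st <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(st$tree), tr)),
                 0, info = paste("tree", i))
  }
})

test_that("NJ matches UPGMA topology on ultrametric distances", {
  set.seed(47)
  pts <- matrix(rnorm(14), ncol = 2,
                dimnames = list(paste0("t", 1:7), NULL))
  hc <- hclust(dist(pts), method = "average")
  D <- cophenetic(hc)
  upgma <- ape::unroot(ape::as.phylo(hc))
  st <- nj_tree(as.matrix(D))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(st$tree), upgma)),
               0)
})

test_that("bootstrap supports are deterministic and order-invariant", {
  set.seed(53)
  terms <- simulate_terminal_domains(n_families = 4, n_species = 3,
                                     len = 80, within = 0.03,
                                     between = 0.3, seed = 9)
  msa <- setNames(terms$sequence, terms$taxon)  # equal lengths
  b1 <- bootstrap_tree(msa, reps = 30, seed = 5)
  b2 <- bootstrap_tree(msa, reps = 30, seed = 5)
  expect_identical(b1$tree$node.label, b2$tree$node.label)
  expect_true(all(b1$supports >= 0 & b1$supports <= 100))
  # permuting taxa leaves the supports of the decisive family edges
  # unchanged (weakly supported edges may flip on replicate-level NJ
  # ties, which is inherent to resampling, not to taxon order)
  perm <- sample(length(msa))
  b3 <- bootstrap_tree(msa[perm], reps = 30, seed = 5)
  fam_support <- function(bt) {
    labs <- setNames(terms$family, terms$taxon)
    pp <- ape::prop.part(bt$tree)
    tips <- bt$tree$tip.label
    vapply(split(names(labs), unname(labs)), function(mem) {
      target <- sort(match(mem, tips))
      for (k in seq_along(pp)) {
        side <- sort(pp[[k]])
        if (identical(side, target) ||
            identical(sort(setdiff(seq_along(tips), side)), target))
          return(bt$supports[k])
      }
      NA_real_
    }, numeric(1))
  }
  expect_equal(fam_support(b3), fam_support(b1))
  # reps = 0 leaves supports unset
  expect_null(bootstrap_tree(msa, reps = 0)$supports)
})

test_that("monophyly is read off edge bipartitions", {
  t1 <- "((a1:1,a2:1):1,(b1:1,b2:1):1);"
  labs <- c(a1 = "a", a2 = "a", b1 = "b", b2 = "b")
  r1 <- monophyly_report(t1, labs)
  expect_true(all(r1$monophyletic))
  t2 <- "((a1:1,b1:1):1,(a2:1,b2:1):1);"
  r2 <- monophyly_report(t2, labs)
  expect_false(any(r2$monophyletic))
  # single-member families are trivially monophyletic
  t3 <- "((a1:1,b1:1):1,c1:1);"
  r3 <- monophyly_report(t3, c(a1 = "a", b1 = "b", c1 = "c"))
  expect_true(all(r3$monophyletic))
})

test_that("newick round-trip preserves topology", {
  set.seed(59)
  tr <- ape::rtree(8)
  d <- withr::local_tempdir()
  p <- file.path(d, "t.nwk")
  write_support_tree(structure(list(tree = tr), class = "support_tree"),
                     p)
  back <- ape::read.tree(p)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(back), ape::unroot(tr))),
               0)
})
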