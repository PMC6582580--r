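random_cds_set <- function(n, len_aa, seed, rate = 0.15) {
  gulotrace:::.with_seed(seed, {
    anc <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        len_aa, TRUE), collapse = "")
    prots <- vapply(seq_len(n), function(i)
      gulotrace:::.mutate_protein(anc, rate), character(1))
    stats::setNames(vapply(prots, gulotrace:::.back_translate, character(1)),
                    paste0("t", seq_len(n)))
  })
}

test_that("codon alignment degaps to the input CDS for every record", {
  two <- c(a = "ATGCATTGGGCTAAA", b = "ATGCATTGGGCTAAA")
  aln <- align_codons(two)
  expect_false(any(grepl("-", aln$nuc)))
  for (seed in 1:6) {
    cds <- random_cds_set(sample(3:6, 1), sample(20:60, 1), seed)
    aln <- align_codons(cds)
    for (id in names(cds)) {
      expect_identical(gsub("-", "", aln$nuc[[id]], fixed = TRUE), cds[[id]])
      # gaps come in whole codons
      gaps <- regmatches(aln$nuc[[id]], gregexpr("-+", aln$nuc[[id]]))[[1]]
      if (length(gaps)) expect_true(all(nchar(gaps) %% 3 == 0))
    }
    widths <- nchar(aln$nuc)
    expect_equal(length(unique(widths)), 1)
  }
  expect_error(align_codons(c(x = "ATGTAAATG")), "internal stop")
  expect_error(align_codons(c(x = "ATGC")), "multiple of 3")
})

test_that("a clean 3-codon insertion aligns as one length-9 gap", {
  base <- random_cds_set(1, 40, 99)[[1]]
  with_ins <- paste0(substr(base, 1, 60), "GCTGCAGCC", substring(base, 61))
  aln <- align_codons(c(a = base, b = with_ins))
  expect_identical(gsub("-", "", aln$nuc[["a"]], fixed = TRUE), base)
  gaps <- regmatches(aln$nuc[["a"]], gregexpr("-+", aln$nuc[["a"]]))[[1]]
  expect_equal(gaps, "---------")
  expect_equal(regexpr("-", aln$nuc[["a"]], fixed = TRUE)[1], 61)
})

test_that("column support scores pairwise consistency on a 0-9 scale", {
  ident <- random_cds_set(4, 25, 7, rate = 0)
  aln <- align_codons(ident)
  cs <- column_support(aln)
  expect_true(all(cs$support == 9))
  expect_equal(length(cs$kept), nchar(aln$prot[[1]]))
  # a hand-built column of mutually low-scoring residues is dropped
  prot <- c(a = "MKGW", b = "MKPW", c = "MKDW", d = "MKWW")
  cds <- vapply(prot, function(p)
    gulotrace:::.with_seed(1, gulotrace:::.back_translate(p)), character(1))
  aln2 <- align_codons(cds)
  cs2 <- column_support(aln2)
  # column 3: G/P/D/W disagree and score <= 0 pairwise under BLOSUM62
  expect_lte(cs2$support[3], 2)
  expect_false(3 %in% cs2$kept)
  expect_true(all(c(1, 2, 4) %in% cs2$kept))
  # filtering is idempotent
  cs3 <- column_support(cs2$alignment)
  expect_equal(length(cs3$kept), nchar(cs2$alignment$prot[[1]]))
})

test_that("neighbour joining recovers three-point and additive trees", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), 1)
  expect_equal(unname(bl["B"]), 1)
  expect_equal(unname(bl["C"]), 3)
  set.seed(81)
  for (i in 1:20) {
    ntip <- sample(4:10, 1)
    t0 <- ape::rtree(ntip)
    D0 <- ape::cophenetic.phylo(t0)
    t1 <- nj_tree(D0)
    expect_equal(ape::dist.topo(ape::unroot(t0), ape::unroot(t1)),
                 structure(0, names = "PH85"), ignore_attr = TRUE)
  }
})

test_that("outgroup-rooted placement separates ingroup and external queries", {
  fam <- fix_family
  near <- gulotrace:::.with_seed(91, gulotrace:::.mutate_protein(
    fam$animal[[1]], 0.05, fam$motif_pos))
  far <- gulotrace:::.with_seed(92, paste(
    sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 120, TRUE),
    collapse = ""))
  cds <- c(fam$animal_cds, fam$fungal_cds,
           near_query = gulotrace:::.with_seed(93,
             gulotrace:::.back_translate(near)),
           far_query = gulotrace:::.with_seed(94,
             gulotrace:::.back_translate(far)))
  tree <- nj_tree(align_codons(cds))
  verdict <- place_and_classify(tree, c("near_query", "far_query"),
                                names(fam$animal_cds),
                                names(fam$fungal_cds))
  expect_true(verdict$confirmed[verdict$id == "near_query"])
  expect_false(verdict$confirmed[verdict$id == "far_query"])
  expect_error(place_and_classify(tree, "near_query",
                                  names(fam$animal_cds), "missing_tip"),
               "not in tree")
})

test_that("burn-in arithmetic is exact", {
  expect_identical(burnin_count(5e6, 100, 0.25), 12500L)
  expect_identical(burnin_count(1000, 10, 0.25), 25L)
  expect_identical(burnin_count(1000, 10, 0), 0L)
  expect_error(burnin_count(10, 100, 0.25))
})

test_that("psrf matches the Gelman-Rubin formula and coda's diagnostic", {
  expect_equal(psrf(cbind(rep(3, 10), rep(3, 10))), 1.0)
  # hand arithmetic: identical non-constant chains, B = 0
  x <- c(1, 2, 3, 4)
  expect_equal(psrf(cbind(x, x)), sqrt(3 / 4))
  # dispersed chains blow up the statistic
  set.seed(5)
  bad <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(psrf(bad), 1.1)
  # stationary chains sit at 1.00 and agree with coda
  set.seed(6)
  ch <- cbind(rnorm(5000), rnorm(5000))
  expect_equal(psrf(ch), 1, tolerance = 0.01)
  cd <- coda::gelman.diag(coda::mcmc.list(coda::mcmc(ch[, 1]),
                                          coda::mcmc(ch[, 2])),
                          autoburnin = FALSE)$psrf[1]
  expect_equal(psrf(ch), cd, tolerance = 0.02)
})
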