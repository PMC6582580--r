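mk_call <- function(species, status) {
  structure(list(species = species, status = status, evidence = list()),
            class = "species_call")
}

mk_model <- function(motif = "HWAK", acceptable = TRUE,
                     contaminated = FALSE) {
  list(motif = motif, acceptable = acceptable, contaminated = contaminated,
       protein = if (motif == "none") "MAAA" else
         paste0("M", sub("x", "A", motif), "LL"))
}

no_hsps <- data.frame(hsp_id = character(0), scaffold_id = character(0),
                      q_start = integer(0), q_end = integer(0))
some_hsps <- function(scaffolds, q0, q1) {
  data.frame(hsp_id = paste0("h", seq_along(scaffolds)),
             scaffold_id = scaffolds, q_start = q0, q_end = q1)
}

test_that("contamination screening needs a bacterial best hit with margin", {
  verdict <- screen_contamination(fix_family$bacterial_cds[[1]],
                                  fix_panel, fix_labels)
  expect_true(verdict$contaminated)
  expect_equal(verdict$best_label, "bacterial")
  planted <- gulotrace:::.with_seed(
    61, gulotrace:::.back_translate(fix_species_protein(601)))
  verdict2 <- screen_contamination(planted, fix_panel, fix_labels)
  expect_false(verdict2$contaminated)
  expect_equal(verdict2$best_label, "animal")
  expect_error(screen_contamination(planted, fix_panel,
                                    rep("animal", length(fix_panel))),
               "bacterial")
})

test_that("species calls follow the documented precedence", {
  q <- fix_family$query
  # acceptable uncontaminated HWAK model -> PRESENT
  call <- call_species("sp", list(mk_model()), some_hsps("s1", 0, 100), q)
  expect_equal(call$status, "PRESENT")
  # HWGK-only models are never PRESENT
  call <- call_species("sp", list(mk_model("HWGK")),
                       some_hsps("s1", 0, 100), q)
  expect_false(call$status == "PRESENT")
  # only contaminated models -> CONTAMINATION
  call <- call_species("sp", list(mk_model(contaminated = TRUE)),
                       some_hsps("s1", 0, 100), q)
  expect_equal(call$status, "CONTAMINATION")
  # scattered evidence without a single-scaffold model -> INCONCLUSIVE
  call <- call_species("sp", list(),
                       some_hsps(c("s1", "s2", "s3"), c(0, 40, 80),
                                 c(40, 80, 120)), q)
  expect_equal(call$status, "INCONCLUSIVE")
  # no homology -> ABSENT; residual coverage -> ABSENT
  expect_equal(call_species("sp", list(), no_hsps, q)$status, "ABSENT")
  call <- call_species("sp", list(), some_hsps("s1", 0, 20), q)
  expect_equal(call$status, "ABSENT")
  # substantial single-scaffold homology but no model -> INCONCLUSIVE
  call <- call_species("sp", list(), some_hsps("s1", 0, 80), q)
  expect_equal(call$status, "INCONCLUSIVE")
  # pure function: repeated evaluation gives identical output
  a <- call_species("sp", list(mk_model()), some_hsps("s1", 0, 100), q)
  b <- call_species("sp", list(mk_model()), some_hsps("s1", 0, 100), q)
  expect_identical(a, b)
})

test_that("lineage calls require three absent species and no present one", {
  abs4 <- lapply(paste0("m", 1:4), mk_call, status = "ABSENT")
  expect_equal(call_lineage(abs4, "Mesostigmata")$status, "ABSENT")
  abs2 <- lapply(paste0("m", 1:2), mk_call, status = "ABSENT")
  expect_equal(call_lineage(abs2)$status, "INCONCLUSIVE")
  mix <- c(list(mk_call("a", "PRESENT")),
           lapply(paste0("m", 1:2), mk_call, status = "ABSENT"))
  expect_equal(call_lineage(mix, "Gastropoda")$status, "PRESENT")
  # contamination counts as neither present nor absent
  cont <- c(list(mk_call("r", "CONTAMINATION")),
            lapply(paste0("m", 1:2), mk_call, status = "ABSENT"))
  expect_equal(call_lineage(cont)$status, "INCONCLUSIVE")
})

test_that("Dollo mapping places minimal losses canonically", {
  tr <- parse_newick("((A,B),(C,D));")
  lm <- dollo_losses(tr, c(A = "present", B = "present",
                           C = "absent", D = "absent"))
  expect_equal(lm$n_losses, 1)
  expect_setequal(lm$loss_clades[[1]], c("C", "D"))
  expect_equal(dollo_losses(tr, c(A = "present", B = "present",
                                  C = "present", D = "present"))$n_losses, 0)
  expect_error(dollo_losses(tr, c(Z = "absent")), "not in tree")
})

test_that("Dollo counts equal brute-force enumeration on random trees", {
  set.seed(71)
  for (i in 1:25) {
    ntip <- sample(4:8, 1)
    tr <- ape::rtree(ntip, br = NULL)
    states <- sample(c("present", "absent", "unknown"), ntip, TRUE)
    names(states) <- tr$tip.label
    got <- dollo_losses(tr, states)$n_losses
    want <- oracle_dollo(tr, states)
    expect_equal(got, want, info = paste("tree", i))
    # adding an unknown tip never increases the loss count
    states2 <- states
    states2[sample(which(states != "unknown"), 1)] <- "unknown"
    expect_lte(dollo_losses(tr, states2)$n_losses, got)
  }
})

test_that("the Protostomia lineage matrix yields 4 independent losses", {
  fx <- protostomia_fixture()
  lm <- dollo_losses(fx$tree, fx$states)
  expect_equal(lm$n_losses, 4)
  expect_equal(lm$n_losses, oracle_dollo(fx$tree, fx$states))
  flat <- lm$loss_clades
  expect_true(any(vapply(flat, function(x) identical(x, "Nematoda"),
                         logical(1))))
  expect_true(any(vapply(flat, function(x) identical(x, "Pancrustacea"),
                         logical(1))))
  expect_true(any(vapply(flat, function(x) identical(x, "Platyhelminthes"),
                         logical(1))))
  expect_true(any(vapply(flat, function(x) setequal(x, c("Bivalvia",
                                                         "Cephalopoda")),
                         logical(1))))
})

test_that("callogram rendering maps statuses to the published colours", {
  tree <- parse_newick(readLines(system.file(
    "extdata", "parasitiformes_tree.nwk", package = "gulotrace")))
  tab_in <- utils::read.delim(system.file(
    "extdata", "parasitiformes_calls.tsv", package = "gulotrace"))
  calls <- lapply(seq_len(nrow(tab_in)), function(i)
    mk_call(tab_in$species[i], tab_in$status[i]))
  out <- render_callogram(tree, calls)
  expect_setequal(out$species, tab_in$species)
  expect_false(any(is.na(out$colour)))
  expect_equal(out$colour[out$species == "I_scapularis"], "green")
  expect_equal(out$colour[out$species == "R_microplus"], "orange")
  expect_equal(out$colour[out$species == "I_ricinus"], "blue")
  expect_equal(out$colour[out$species == "V_destructor"], "red")
  # the four Mesostigmata ABSENT calls make the lineage ABSENT
  meso <- calls[tab_in$order == "Mesostigmata"]
  expect_equal(call_lineage(meso, "Mesostigmata")$status, "ABSENT")
  expect_error(render_callogram(tree, list()), "no calls")
  expect_error(render_callogram(tree, calls[1:2]), "missing")
})
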