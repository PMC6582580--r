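test_that("HWxK motif scanning and classification follow the variant rules", {
  expect_equal(scan_motif("MHWAKL"), list(pos = 1L, x = "A"))
  expect_equal(scan_motif("MHWGKL"), list(pos = 1L, x = "G"))
  expect_equal(scan_motif("MHWTKL")$x, "T")
  expect_null(scan_motif("MAAAA"))
  expect_null(scan_motif("MHWXKL"))  # X-the-unknown never matches x
  expect_equal(classify_sequence(list(protein = "MHWAKL")), "GULO_CANDIDATE")
  expect_equal(classify_sequence(list(protein = "MHWGKL")), "VAO_OTHER")
  expect_equal(classify_sequence(list(protein = "MHWTKL")), "VAO_OTHER")
  expect_equal(classify_sequence(list(protein = "MAAAA")), "UNCLASSIFIED")
})

test_that("candidate exons respect construction invariants", {
  expect_equal(nrow(candidate_exons(strrep("N", 300),
                                    fix_family$query)), 0)
  # single-exon planted gene: a candidate spans the whole CDS
  prot <- fix_species_protein(501)
  gt <- synth_genome(plant_spec(prot, 1), 2500, 0.4, seed = 3)
  gene <- gt$genes[[1]]
  cands <- candidate_exons(gt$scaffolds[[1]], fix_family$query)
  full <- cands[cands$strand == "+" &
                cands$start == gene$exons$start[1] &
                cands$end == gene$exons$end[1], ]
  expect_equal(nrow(full), 1)
  expect_equal(full$cds_start, 0)
  expect_equal(full$cds_end, nchar(gene$cds))
  expect_equal(max(cands$score), full$score)
  # no candidate interior contains an in-frame stop in its recorded phase
  s <- gt$scaffolds[[1]]
  for (i in seq_len(min(nrow(cands), 40))) {
    cn <- cands[i, ]
    seqs <- if (cn$strand == "+") s else revcomp(s)
    u0 <- cn$cds_start; c0 <- ceiling(u0 / 3) * 3 - u0  # nt to first codon
    codseq <- substr(seqs, cn$start + c0 + 1, cn$start + c0 +
                       3 * ((cn$end - cn$start - c0) %/% 3))
    if (nchar(codseq) >= 3)
      expect_false(grepl("\\*", translate_frame(codseq, 1)),
                   info = paste("candidate", i))
  }
})

test_that("exon chaining equals exhaustive enumeration on small inputs", {
  prot <- fix_species_protein(502)
  for (seed in c(2, 5, 8, 13)) {
    gt <- synth_genome(plant_spec(prot, 2), 2200, 0.4, seed = seed)
    region <- list(sequence = gt$scaffolds[[1]], start = 0L,
                   scaffold_id = "scaffold_1")
    cands <- candidate_exons(region, fix_family$query)
    fw <- cands[cands$strand == "+", , drop = FALSE]
    fw <- fw[order(-fw$score)[seq_len(min(10, nrow(fw)))], , drop = FALSE]
    model <- chain_exons(fw, fix_family$query, region)
    want <- oracle_best_chain(fw, fix_family$query, gt$scaffolds[[1]])
    if (is.null(model)) {
      expect_lt(want, genemodel_params()$chain_min_score)
    } else {
      expect_equal(model$score, want, info = paste("seed", seed))
    }
  }
})

test_that("planted multi-exon genes are recovered exactly via regions", {
  prot <- fix_species_protein(503)
  for (seed in c(21, 22, 23, 24)) {
    ec <- 2 + seed %% 3
    strand <- if (seed %% 2) "+" else "-"
    gt <- synth_genome(plant_spec(prot, ec, strand = strand), 3000, 0.4,
                       seed = seed)
    model <- annotate_region(gt$scaffolds[[1]], fix_family$query)
    expect_false(is.null(model))
    expect_identical(model$cds, gt$genes[[1]]$cds)
    expect_identical(model$strand, strand)
    expect_identical(translate_frame(model$cds, 1), model$protein)
    expect_equal(model$motif, gt$genes[[1]]$motif)
    # emitted introns are canonical on the coding strand
    seqs <- if (strand == "+") gt$scaffolds[[1]] else
      revcomp(gt$scaffolds[[1]])
    regional <- chain_exons(candidate_exons(seqs, fix_family$query),
                            fix_family$query, seqs)
    ex <- regional$exons[order(regional$exons$start), ]
    if (nrow(ex) > 1) {
      for (i in 1:(nrow(ex) - 1)) {
        intr <- substr(seqs, ex$end[i] + 1, ex$start[i + 1])
        expect_match(intr, "^GT.*AG$")
      }
    }
  }
})

test_that("validation flags stops, start codons and coverage correctly", {
  prot <- fix_species_protein(504)
  gt <- synth_genome(plant_spec(prot, 2), 2500, 0.4, seed = 31)
  model <- annotate_region(gt$scaffolds[[1]], fix_family$query)
  model <- validate_model(model, fix_family$query)
  expect_false(model$has_internal_stop)
  expect_gte(model$coverage_frac, 0.95)
  expect_true(model$acceptable)
  # an internal stop voids acceptability
  bad <- model
  bad$protein <- paste0(substr(model$protein, 1, 10), "*",
                        substring(model$protein, 12))
  bad <- validate_model(bad, fix_family$query)
  expect_true(bad$has_internal_stop)
  expect_false(bad$acceptable)
  # a start-codon-less but otherwise complete model stays acceptable
  nostart <- model
  nostart$cds <- substring(model$cds, 4)
  nostart$protein <- substring(model$protein, 2)
  nostart <- validate_model(nostart, fix_family$query)
  expect_false(nostart$has_start_codon)
  expect_true(nostart$acceptable)
})

test_that("lone-ATG genes are annotated without the start codon", {
  prot <- fix_species_protein(505)
  gt <- synth_genome(plant_spec(prot, 3, lone_atg_first_exon = TRUE),
                     3000, 0.4, seed = 41)
  model <- annotate_region(gt$scaffolds[[1]], fix_family$query)
  expect_false(is.null(model))
  # the annotation drops the isolated ATG exon (as real de novo GULO
  # annotations do) but recovers the rest of the CDS exactly
  expect_identical(model$cds, substring(gt$genes[[1]]$cds, 4))
  expect_false(model$has_start_codon)
  expect_true(validate_model(model, fix_family$query)$acceptable)
})
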