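# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code under fixed seeds; nothing is downloaded.

# one synthetic GULO-like family reused across tests
fix_family <- make_gulo_family(20240117)
fix_panel <- c(fix_family$animal_cds, fix_family$bacterial_cds)
fix_labels <- rep(c("animal", "bacterial"),
                  c(length(fix_family$animal_cds),
                    length(fix_family$bacterial_cds)))

# a planted species protein at the family's typical divergence
fix_species_protein <- function(seed) {
  gulotrace:::.with_seed(seed, gulotrace:::.mutate_protein(
    fix_family$ancestor, 0.10, fix_family$motif_pos))
}

# ---- independent oracles -------------------------------------------------

# six-frame Smith-Waterman maximum via Biostrings (independent of the
# package's seeded x-drop search); same matrix and gap model
oracle_sw6 <- function(query, scaffold) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  best <- -Inf
  dna <- Biostrings::DNAString(scaffold)
  for (strand in 1:2) {
    d <- if (strand == 1) dna else Biostrings::reverseComplement(dna)
    for (off in 0:2) {
      n <- length(d) - off
      if (n < 3) next
      aa <- Biostrings::translate(Biostrings::subseq(d, off + 1,
                                                     off + (n %/% 3) * 3),
                                  if.fuzzy.codon = "solve")
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(query), aa, type = "local",
        substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1)
      best <- max(best, Biostrings::score(pa))
    }
  }
  best
}

# exhaustive word-pair seed enumeration (independent of seed_hits)
oracle_seeds <- function(query, target, w, threshold) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  out <- NULL
  for (i in seq_len(length(q) - w + 1L)) {
    for (j in seq_len(length(t) - w + 1L)) {
      sc <- sum(vapply(seq_len(w), function(k)
        BLOSUM62[q[i + k - 1L], t[j + k - 1L]], numeric(1)))
      exact <- all(q[i:(i + w - 1L)] == t[j:(j + w - 1L)])
      if (sc >= threshold || exact)
        out <- rbind(out, c(i - 1L, j - 1L))
    }
  }
  out
}

# exhaustive exon-chain enumeration over candidate subsets (the DP's
# contract, re-derived independently: colinearity, GT-AG introns, phase
# compatibility with junction codons, codon-boundary chain ends)
oracle_best_chain <- function(cands, query, seqs, min_intron = 20L,
                              intron_penalty = 5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  best <- -Inf
  n <- nrow(cands)
  cands <- cands[order(cands$start, cands$end), , drop = FALSE]
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    ch <- cands[idx, , drop = FALSE]
    if (ch$cds_start[1] %% 3L != 0L) next
    if (ch$cds_end[nrow(ch)] %% 3L != 0L) next
    score <- sum(ch$score) - intron_penalty * (nrow(ch) - 1L)
    valid <- TRUE
    if (nrow(ch) > 1L) {
      for (i in 2:nrow(ch)) {
        a <- ch[i - 1L, ]; b <- ch[i, ]
        if (a$end + min_intron > b$start) { valid <- FALSE; break }
        if (a$cds_end > b$cds_start) { valid <- FALSE; break }
        if (substr(seqs, a$end + 1L, a$end + 2L) != "GT" ||
            substr(seqs, b$start - 1L, b$start) != "AG") {
          valid <- FALSE; break
        }
        r <- a$cds_end %% 3L
        if (r == 0L) {
          if ((b$cds_start - a$cds_end) %% 3L != 0L) { valid <- FALSE; break }
          if (b$cds_start > a$cds_end)  # deletion of skipped query codons
            score <- score - (11 + (b$cds_start - a$cds_end) %/% 3L)
        } else {
          if (b$cds_start != a$cds_end) { valid <- FALSE; break }
          codon <- paste0(substr(seqs, a$end - r + 1L, a$end),
                          substr(seqs, b$start + 1L, b$start + 3L - r))
          aa <- translate_frame(codon, 1L)
          if (aa == "*") { valid <- FALSE; break }
          qaa <- substr(query, a$cds_end %/% 3L + 1L, a$cds_end %/% 3L + 1L)
          score <- score + BLOSUM62[qaa, aa]
        }
      }
    }
    if (valid && score > best) best <- score
  }
  best
}

# brute-force minimum Dollo loss count: try all loss-edge subsets of
# increasing size
oracle_dollo <- function(tree, tip_states) {
  states <- rep("unknown", length(tree$tip.label))
  names(states) <- tree$tip.label
  states[names(tip_states)] <- tip_states
  below <- lapply(seq_len(nrow(tree$edge)), function(k) {
    node <- tree$edge[k, 2]
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    ape::extract.clade(tree, node)$tip.label
  })
  present <- names(states)[states == "present"]
  absent <- names(states)[states == "absent"]
  if (length(absent) == 0L) return(0L)
  ne <- nrow(tree$edge)
  for (size in 1:length(absent)) {
    for (comb in utils::combn(ne, size, simplify = FALSE)) {
      cover <- unlist(below[comb])
      if (any(present %in% cover)) next
      counts <- table(factor(cover, levels = absent))
      if (all(counts == 1L) && length(cover[cover %in% absent]) ==
          length(absent) && all(absent %in% cover)) {
        return(size)
      }
    }
  }
  length(absent)
}

# Fig-5-style lineage cladogram with the published presence/absence pattern
protostomia_fixture <- function() {
  tree <- parse_newick(paste0(
    "((Priapulida,(Nematoda,(Tardigrada,((Araneae,Acari),Pancrustacea))))",
    ",(Platyhelminthes,(Annelida,(Brachiopoda,(Gastropoda,",
    "(Bivalvia,Cephalopoda))))));"))
  states <- c(Priapulida = "present", Nematoda = "absent",
              Tardigrada = "unknown", Araneae = "present", Acari = "present",
              Pancrustacea = "absent", Platyhelminthes = "absent",
              Annelida = "present", Brachiopoda = "present",
              Gastropoda = "present", Bivalvia = "absent",
              Cephalopoda = "unknown")
  list(tree = tree, states = states)
}
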