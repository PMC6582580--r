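# Synthetic-data generators.  Every generator takes an explicit seed and is
# byte-deterministic given it; the global RNG stream is left untouched.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.random_dna <- function(n, gc = 0.4) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# random synonymous back-translation of a protein (no trailing stop codon)
.back_translate <- function(protein) {
  tab <- .codon_table()
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  stopifnot(!"*" %in% aas)
  codons <- vapply(aas, function(a) {
    opts <- names(tab)[tab == a]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

.AA20 <- setdiff(.AA_ALPHABET, c("X", "*"))

.find_motifs <- function(protein) {
  # all HWxK sites (x = any of the 20 amino acids), 0-based start positions
  m <- gregexpr("HW[A-Z]K", protein, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# point-mutate a protein at `rate`, keeping a motif site intact and making
# sure no second HWxK site is created
.mutate_protein <- function(protein, rate, protect = integer(0)) {
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  keep <- unique(unlist(lapply(protect, function(p) p + 1:4)))
  idx <- setdiff(seq_along(aas), keep)
  hit <- idx[stats::runif(length(idx)) < rate]
  for (i in hit) aas[i] <- sample(setdiff(.AA20, aas[i]), 1L)
  out <- paste(aas, collapse = "")
  extra <- setdiff(.find_motifs(out), protect)
  for (p in extra) {  # break accidental motifs at the tryptophan
    aas[p + 2L] <- sample(setdiff(.AA20, c("W", aas[p + 2L])), 1L)
    out <- paste(aas, collapse = "")
  }
  out
}

#' Generate a synthetic GULO-like protein family
#'
#' Builds, from one ancestral HWAK-motif protein, the reference panels the
#' pipeline needs: a search query, animal GULO references, a fungal
#' outgroup, and bacterial decoys (HWAK-bearing but deeply diverged,
#' standing in for bacterial L-gulonolactone dehydrogenase-like genes that
#' show up as assembly contamination).  Divergence rates are per-site
#' substitution probabilities from the ancestor.
#'
#' @param seed Integer seed.
#' @param length Protein length in residues (desk-scale default 120).
#' @param n_animal,n_fungal,n_bacterial Panel sizes.
#' @return List with elements `ancestor`, `query`, `animal`, `fungal`,
#'   `bacterial` (named protein vectors), the matching back-translated CDS
#'   panels `animal_cds`, `fungal_cds`, `bacterial_cds`, and `motif_pos`
#'   (0-based motif start in the ancestor).
#' @export
make_gulo_family <- function(seed, length = 120L, n_animal = 3L,
                             n_fungal = 2L, n_bacterial = 2L) {
  .with_seed(seed, {
    pos <- as.integer(length / 2)
    aas <- sample(.AA20, length, replace = TRUE)
    aas[1] <- "M"
    aas[pos + 1:4] <- c("H", "W", "A", "K")
    anc <- paste(aas, collapse = "")
    anc <- .mutate_protein(anc, 0, protect = pos)  # clear accidental motifs
    mk <- function(n, rate, prefix) {
      v <- vapply(seq_len(n), function(i) .mutate_protein(anc, rate, pos),
                  character(1))
      stats::setNames(v, paste0(prefix, seq_len(n)))
    }
    animal <- mk(n_animal, 0.10, "animal_ref_")
    fungal <- mk(n_fungal, 0.25, "fungal_ref_")
    bacterial <- mk(n_bacterial, 0.35, "bacterial_ref_")
    list(ancestor = anc,
         query = .mutate_protein(anc, 0.05, pos),
         animal = animal, fungal = fungal, bacterial = bacterial,
         animal_cds = vapply(animal, .back_translate, character(1)),
         fungal_cds = vapply(fungal, .back_translate, character(1)),
         bacterial_cds = vapply(bacterial, .back_translate, character(1)),
         motif_pos = pos)
  })
}

#' Describe a gene to plant in a synthetic genome
#'
#' @param protein Protein to encode.  Positive plants must contain exactly
#'   one HWxK site; null plants (`motif_variant = "none"`) none.  No `*`.
#' @param exon_count Number of coding exons (>= 1).
#' @param intron_length_range Intron length bounds in nt, minimum >= 20
#'   (room for GT...AG and a branch region).
#' @param strand `"+"` or `"-"`.
#' @param lone_atg_first_exon If `TRUE` the first coding exon encodes the
#'   ATG codon only, mirroring the structure seen in real GULO genes where
#'   de novo annotations lack a start codon because the first exon is just
#'   the ATG.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(protein, exon_count = 3L,
                       intron_length_range = c(50L, 300L), strand = "+",
                       lone_atg_first_exon = FALSE) {
  stopifnot(exon_count >= 1L, intron_length_range[1] >= 20L,
            intron_length_range[1] <= intron_length_range[2],
            strand %in% c("+", "-"))
  if (grepl("*", protein, fixed = TRUE)) stop("planted protein contains '*'")
  motifs <- .find_motifs(protein)
  variant <- if (length(motifs) == 0L) "none"
    else substr(protein, motifs[1] + 3L, motifs[1] + 3L)
  variant <- switch(variant, A = "HWAK", G = "HWGK", none = "none",
                    paste0("HW", variant, "K"))
  if (variant != "none" && length(motifs) != 1L)
    stop("positive plants must contain exactly one HWxK site")
  if (lone_atg_first_exon && substr(protein, 1L, 1L) != "M")
    stop("lone-ATG first exon requires a protein starting with M")
  structure(list(protein = protein, exon_count = as.integer(exon_count),
                 intron_length_range = as.integer(intron_length_range),
                 strand = strand, motif_variant = variant,
                 lone_atg_first_exon = lone_atg_first_exon),
            class = "plant_spec")
}

# split a CDS of length L into `k` exon lengths; allows codon-interior
# points; avoids any single exon dominating the CDS so that fragmented
# variants cannot keep most of the gene on one scaffold
.split_cds <- function(L, k, min_exon = 30L, lone_atg = FALSE) {
  first <- integer(0)
  if (lone_atg) {
    first <- 3L
    L <- L - 3L
    k <- k - 1L
    if (k == 0L) return(first)
  }
  if (k == 1L) return(c(first, L))
  if (L < k * min_exon) stop("impossible packing: CDS too short for exon count")
  for (try in 1:200) {
    cuts <- sort(sample(seq(min_exon, L - min_exon), k - 1L))
    lens <- diff(c(0L, cuts, L))
    if (all(lens >= min_exon) && (k < 3L || max(lens) / L < 0.45)) {
      return(c(first, lens))
    }
  }
  stop("impossible packing: could not split CDS under the length constraints")
}

#' Plant a gene in a synthetic genome
#'
#' Back-translates the protein, splits the CDS into exons (at codon-interior
#' or codon-boundary points, recorded in the truth annotation), joins them
#' with canonical GT...AG introns, and embeds the cassette in iid background
#' sequence of the requested GC.  Byte-deterministic given the seed.
#'
#' @param spec A [plant_spec()], or `NULL` for a gene-free (absent-mode)
#'   genome of pure background.
#' @param background_length Total background nt around/instead of the gene.
#' @param gc Background GC fraction (0 < gc < 1).
#' @param seed Integer seed.
#' @return A `genome_truth` list: `scaffolds` (named nucleotide vector),
#'   `genes` (list of truth gene models with `exons`, `cds`, `protein`,
#'   `motif`, `strand`, `has_start_codon`), and `mode`.
#' @export
synth_genome <- function(spec, background_length = 4000L, gc = 0.4, seed = 1L) {
  stopifnot(gc > 0, gc < 1)
  .with_seed(seed, {
    if (is.null(spec)) {
      sc <- stats::setNames(.random_dna(background_length, gc), "scaffold_1")
      return(structure(list(scaffolds = sc, genes = list(), mode = "absent"),
                       class = "genome_truth"))
    }
    cds <- .back_translate(spec$protein)
    L <- nchar(cds)
    lens <- .split_cds(L, spec$exon_count, lone_atg = spec$lone_atg_first_exon)
    ends <- cumsum(lens)
    starts <- c(0L, ends[-length(ends)])
    exon_seqs <- substring(cds, starts + 1L, ends)
    n_intron <- length(lens) - 1L
    introns <- character(0)
    if (n_intron > 0L) {
      ilens <- sample(seq(spec$intron_length_range[1],
                          spec$intron_length_range[2]), n_intron, replace = TRUE)
      introns <- vapply(ilens, function(n)
        paste0("GT", .random_dna(n - 4L, gc), "AG"), character(1))
    }
    cassette <- exon_seqs[1]
    for (i in seq_len(n_intron)) {
      cassette <- paste0(cassette, introns[i], exon_seqs[i + 1L])
    }
    if (background_length < nchar(cassette))
      stop("impossible packing: background shorter than the planted gene")
    left_n <- sample.int(background_length - 1L, 1L)
    right_n <- background_length - left_n
    ins <- if (spec$strand == "+") cassette else revcomp(cassette)
    scaffold <- paste0(.random_dna(left_n, gc), ins, .random_dna(right_n, gc))
    # forward-strand exon coordinates (0-based half-open)
    off <- left_n
    if (spec$strand == "+") {
      istarts <- off + starts + c(0L, cumsum(nchar(introns)))
      ex <- data.frame(start = istarts, end = istarts + lens)
    } else {
      cass_len <- nchar(cassette)
      istarts <- starts + c(0L, cumsum(nchar(introns)))  # within cassette, 5'->3'
      ex <- data.frame(start = off + cass_len - (istarts + lens),
                       end = off + cass_len - istarts)
    }
    gene <- list(gene_id = "planted_gene_1", scaffold_id = "scaffold_1",
                 strand = spec$strand, exons = ex, cds = cds,
                 protein = spec$protein, motif = spec$motif_variant,
                 has_start_codon = substr(cds, 1L, 3L) == "ATG",
                 lone_atg_first_exon = spec$lone_atg_first_exon)
    structure(list(scaffolds = stats::setNames(scaffold, "scaffold_1"),
                   genes = list(gene), mode = "intact"),
              class = "genome_truth")
  })
}

#' Fragment a synthetic assembly so exons scatter across scaffolds
#'
#' Cuts the gene-bearing scaffold inside introns so the planted exons end up
#' on at least three distinct scaffolds, emulating assemblies where a
#' translated search is scattered across many genomic scaffolds and
#' presence cannot be confidently inferred.
#'
#' @param gt An intact `genome_truth`.
#' @param pieces Number of scaffolds to spread the exons over (>= 3).
#' @param seed Integer seed.
#' @return The fragmented `genome_truth` (mode `"fragmented"`); truth exons
#'   carry per-exon scaffold ids.
#' @export
fragment_assembly <- function(gt, pieces = 3L, seed = 1L) {
  stopifnot(inherits(gt, "genome_truth"), gt$mode == "intact", pieces >= 3L)
  gene <- gt$genes[[1]]
  k <- nrow(gene$exons)
  if (pieces > k) stop("pieces exceeds the number of exon-bearing segments")
  .with_seed(seed, {
    ex <- gene$exons[order(gene$exons$start), , drop = FALSE]
    # cut points inside the introns between consecutive exon blocks; choose
    # the pieces-1 widest introns so every piece keeps flanking context
    gaps <- data.frame(after = seq_len(k - 1L),
                       mid = floor((ex$end[-k] + ex$start[-1L]) / 2))
    wid <- ex$start[-1L] - ex$end[-k]
    sel <- gaps[order(-wid)[seq_len(pieces - 1L)], , drop = FALSE]
    cuts <- sort(sel$mid)
    seqfull <- gt$scaffolds[[gene$scaffold_id]]
    bounds <- c(0L, cuts, nchar(seqfull))
    pieces_seq <- substring(seqfull, bounds[-length(bounds)] + 1L, bounds[-1L])
    ids <- paste0("scaffold_frag_", seq_along(pieces_seq))
    scaffolds <- stats::setNames(pieces_seq, ids)
    # reassign exon coordinates to their pieces
    piece_of <- findInterval(ex$start, bounds, left.open = FALSE)
    ex$scaffold_id <- ids[piece_of]
    ex$start <- ex$start - bounds[piece_of]
    ex$end <- ex$end - bounds[piece_of]
    gene$exons <- ex
    gene$scaffold_id <- NA_character_
    structure(list(scaffolds = scaffolds, genes = list(gene),
                   mode = "fragmented"), class = "genome_truth")
  })
}

#' Add a bacterial-contaminant scaffold to a synthetic assembly
#'
#' Appends a scaffold carrying an intron-less, near-identical (>= 98%
#' identity) copy of a bacterial reference CDS, emulating assemblies whose
#' apparent GULO-like hit is genome contamination with high homology to a
#' bacterial CDS.
#'
#' @param gt A `genome_truth` (any mode except `"contaminated"`).
#' @param bacterial_ref A single named bacterial CDS (from
#'   [make_gulo_family()]'s `bacterial_cds`).
#' @param seed Integer seed.
#' @return The `genome_truth` with the extra scaffold, mode
#'   `"contaminated"`, and `contaminant_scaffold` recorded.
#' @export
contaminate <- function(gt, bacterial_ref, seed = 1L) {
  stopifnot(inherits(gt, "genome_truth"), length(bacterial_ref) == 1L)
  .with_seed(seed, {
    s <- strsplit(bacterial_ref[[1]], "", fixed = TRUE)[[1]]
    n_mut <- floor(0.01 * length(s))
    if (n_mut > 0L) {
      at <- sample(length(s), n_mut)
      for (i in at) {
        old <- s[i]
        codon_start <- i - (i - 1L) %% 3L
        aa_old <- .codon_table()[paste(s[codon_start:(codon_start + 2L)],
                                       collapse = "")]
        for (base in sample(setdiff(c("A", "C", "G", "T"), old))) {
          s[i] <- base  # synonymous-only: the contaminant ORF stays intact
          codon <- paste(s[codon_start:(codon_start + 2L)], collapse = "")
          if (identical(unname(.codon_table()[codon]), unname(aa_old))) break
          s[i] <- old
        }
      }
    }
    copy <- paste(s, collapse = "")
    scaf <- paste0(.random_dna(300L, 0.5), copy, .random_dna(300L, 0.5))
    scaffolds <- c(gt$scaffolds, stats::setNames(scaf, "scaffold_contam"))
    structure(list(scaffolds = scaffolds, genes = gt$genes,
                   mode = "contaminated",
                   contaminant_scaffold = "scaffold_contam",
                   contaminant_source = names(bacterial_ref)),
              class = "genome_truth")
  })
}

#' Generate a synthetic HPLC chromatogram
#'
#' Signal = low-order polynomial baseline + Gaussian peaks + iid noise.
#' Each planted peak's realised area is `response * conc` jittered by a
#' relative Gaussian error of `area_cv`, so replicate seeds scatter around
#' the calibration line the way injection replicates do.
#'
#' @param peaks Data frame with columns `rt` (retention time, s) and `conc`
#'   (concentration, uM); `conc` must be >= 0.
#' @param response Detector response in area units (a.u.*s) per uM.
#' @param noise_sd Additive trace noise sd (a.u.).
#' @param area_cv Relative sd of the realised peak area (default 1%).
#' @param seed Integer seed.
#' @param times Time grid in seconds (strictly increasing).
#' @param peak_width Gaussian peak sd in seconds.
#' @param baseline Polynomial drift coefficients (intercept, slope, ...).
#' @return A `chrom_truth` list: `times`, `signal`, `peaks` (with realised
#'   `area`), plus the generating parameters.
#' @export
synth_chromatogram <- function(peaks, response = 2, noise_sd = 0.005,
                               area_cv = 0.01, seed = 1L,
                               times = seq(0, 600, by = 0.5), peak_width = 4,
                               baseline = c(0.02, 2e-5)) {
  stopifnot(all(diff(times) > 0), response > 0)
  if (nrow(peaks) > 0 && any(peaks$conc < 0)) stop("negative concentration")
  if (nrow(peaks) > 0 &&
      (min(peaks$rt) < min(times) || max(peaks$rt) > max(times)))
    stop("peak retention time outside the time grid")
  .with_seed(seed, {
    signal <- as.vector(outer(times, seq_along(baseline) - 1L, `^`) %*% baseline)
    areas <- numeric(nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      a <- response * peaks$conc[i]
      if (a > 0) a <- a * (1 + stats::rnorm(1, 0, area_cv))
      areas[i] <- max(a, 0)
      signal <- signal + areas[i] *
        stats::dnorm(times, mean = peaks$rt[i], sd = peak_width)
    }
    signal <- signal + stats::rnorm(length(times), 0, noise_sd)
    pk <- peaks
    pk$area <- areas
    structure(list(times = times, signal = signal, peaks = pk,
                   response = response, noise_sd = noise_sd,
                   peak_width = peak_width, baseline = baseline),
              class = "chrom_truth")
  })
}
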