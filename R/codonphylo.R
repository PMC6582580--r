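# Codon-aware alignment (translate - align - backtranslate), per-column
# support filtering, a neighbour-joining stand-in for Bayesian tree
# inference, outgroup-rooted ortholog placement, and MCMC run diagnostics.

.prot_of_cds <- function(cds, id) {
  if (nchar(cds) %% 3L != 0L)
    stop(sprintf("record '%s': CDS length not a multiple of 3", id))
  p <- translate_frame(cds, 1L)
  if (grepl("\\*.", p))
    stop(sprintf("record '%s': CDS has an internal stop codon", id))
  sub("\\*$", "", p)
}

# mean-of-pairs column score matrix between two profiles (character
# matrices, rows = sequences); gap-containing pairs contribute 0
.profile_colscores <- function(A, B) {
  M <- .blosum62()
  letters <- rownames(M)
  count_mat <- function(P) {
    t(apply(P, 2, function(col) {
      col <- col[col != "-"]
      tabulate(match(col, letters), nbins = length(letters))
    }))
  }
  CA <- count_mat(A)
  CB <- count_mat(B)
  (CA %*% M %*% t(CB)) / (nrow(A) * nrow(B))
}

#' Codon-aware multiple alignment of a CDS set
#'
#' Sequences are aligned at the amino-acid level (iterative progressive
#' alignment: pairwise global alignments give a guide tree, profiles are
#' merged by a sum-of-pairs dynamic program with affine gaps) and the
#' corresponding nucleotide alignment is obtained by threading each
#' record's codons through its aligned protein.  Gap runs in the
#' nucleotide alignment therefore always have length divisible by 3, and
#' degapping any record returns its input CDS exactly.
#'
#' @param cds_set Named vector of CDS strings, each of length divisible by
#'   3 and free of internal stop codons (a trailing stop codon is trimmed).
#' @return A `codon_alignment` list: `nuc` (aligned CDS), `prot` (aligned
#'   proteins), `cds` (trimmed inputs).
#' @export
align_codons <- function(cds_set) {
  n <- length(cds_set)
  stopifnot(n >= 1L, !is.null(names(cds_set)))
  ids <- names(cds_set)
  prots <- vapply(seq_len(n), function(i)
    .prot_of_cds(cds_set[[i]], ids[i]), character(1))
  cds_trim <- vapply(seq_len(n), function(i) {
    substr(cds_set[[i]], 1L, 3L * nchar(prots[i]))
  }, character(1))
  names(prots) <- names(cds_trim) <- ids
  prof <- lapply(prots, function(p)
    matrix(strsplit(p, "", fixed = TRUE)[[1]], nrow = 1))
  members <- as.list(seq_len(n))
  if (n > 1L) {
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(prots[i]), Biostrings::AAString(prots[j]),
          type = "global", substitutionMatrix = .blosum62(),
          gapOpening = 11, gapExtension = 1)
        D[i, j] <- D[j, i] <- 1 - Biostrings::pid(pa) / 100
      }
    }
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    node_prof <- prof
    node_members <- members
    merged_prof <- list(); merged_members <- list()
    get_node <- function(k) {
      if (k < 0) list(p = node_prof[[-k]], m = node_members[[-k]])
      else list(p = merged_prof[[k]], m = merged_members[[k]])
    }
    for (step in seq_len(nrow(hc$merge))) {
      a <- get_node(hc$merge[step, 1])
      b <- get_node(hc$merge[step, 2])
      S <- .profile_colscores(a$p, b$p)
      al <- cpp_profile_align(S, 11, 1)
      L <- length(al$a)
      newp <- matrix("-", nrow(a$p) + nrow(b$p), L)
      newp[seq_len(nrow(a$p)), al$a > 0] <- a$p[, al$a[al$a > 0], drop = FALSE]
      newp[nrow(a$p) + seq_len(nrow(b$p)), al$b > 0] <-
        b$p[, al$b[al$b > 0], drop = FALSE]
      merged_prof[[step]] <- newp
      merged_members[[step]] <- c(a$m, b$m)
    }
    final <- get_node(nrow(hc$merge))
    # restore original record order
    amat <- final$p[match(seq_len(n), unlist(final$m)), , drop = FALSE]
  } else {
    amat <- prof[[1]]
  }
  aligned_prot <- apply(amat, 1, paste, collapse = "")
  names(aligned_prot) <- ids
  aligned_nuc <- vapply(seq_len(n), function(i) {
    codons <- substring(cds_trim[i], seq(1L, nchar(cds_trim[i]), 3L),
                        seq(3L, nchar(cds_trim[i]), 3L))
    cols <- strsplit(aligned_prot[i], "", fixed = TRUE)[[1]]
    out <- character(length(cols))
    ci <- 0L
    for (k in seq_along(cols)) {
      if (cols[k] == "-") out[k] <- "---"
      else { ci <- ci + 1L; out[k] <- codons[ci] }
    }
    paste(out, collapse = "")
  }, character(1))
  names(aligned_nuc) <- ids
  structure(list(nuc = aligned_nuc, prot = aligned_prot, cds = cds_trim),
            class = "codon_alignment")
}

#' Per-codon column support and support filtering
#'
#' Support for a codon column is `round(9 * f)` where f is the fraction of
#' record pairs whose residues in that protein column are identical or
#' score positively under BLOSUM62 (pairs involving a gap never support a
#' column).  Filtering keeps columns with support of at least `min_support`
#' ("above two" in the published procedure, i.e. >= 3 on the 0-9 scale).
#'
#' @param aln A `codon_alignment` with at least 3 records.
#' @param min_support Minimum retained support (default 3).
#' @return List: `support` (integer per column), `kept` (column indices),
#'   `alignment` (the filtered `codon_alignment`).
#' @export
column_support <- function(aln, min_support = 3L) {
  stopifnot(inherits(aln, "codon_alignment"), length(aln$prot) >= 3L)
  M <- .blosum62()
  P <- do.call(rbind, strsplit(aln$prot, "", fixed = TRUE))
  n <- nrow(P)
  npairs <- n * (n - 1L) / 2L
  pairs <- utils::combn(n, 2L)
  support <- vapply(seq_len(ncol(P)), function(k) {
    col <- P[, k]
    good <- 0L
    for (p in seq_len(ncol(pairs))) {
      a <- col[pairs[1, p]]; b <- col[pairs[2, p]]
      if (a == "-" || b == "-") next
      if (a == b || M[a, b] > 0) good <- good + 1L
    }
    as.integer(round(9 * good / npairs))
  }, integer(1))
  kept <- which(support >= min_support)
  sub_nuc <- vapply(aln$nuc, function(s) {
    codons <- substring(s, 3L * kept - 2L, 3L * kept)
    paste(codons, collapse = "")
  }, character(1))
  sub_prot <- vapply(aln$prot, function(s)
    paste(substring(s, kept, kept), collapse = ""), character(1))
  filtered <- structure(list(nuc = sub_nuc, prot = sub_prot,
                             cds = vapply(sub_nuc, function(s)
                               gsub("-", "", s, fixed = TRUE), character(1))),
                        class = "codon_alignment")
  list(support = support, kept = kept, alignment = filtered)
}

#' Neighbour-joining tree from a codon alignment
#'
#' Distances are protein p-distances over the support-filtered columns
#' (fraction of differing residues among positions where both records are
#' ungapped); the tree is standard neighbour joining, which recovers
#' additive distance matrices exactly.  A distance matrix may be supplied
#' directly.
#'
#' @param x A `codon_alignment` or a symmetric distance matrix with
#'   dimnames.
#' @param filter Apply [column_support()] filtering first (default TRUE
#'   when 3 or more records).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(x, filter = TRUE) {
  if (inherits(x, "codon_alignment")) {
    stopifnot(length(x$prot) >= 3L)
    aln <- if (filter) column_support(x)$alignment else x
    P <- do.call(rbind, strsplit(aln$prot, "", fixed = TRUE))
    n <- nrow(P)
    D <- matrix(0, n, n, dimnames = list(names(aln$prot), names(aln$prot)))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ok <- P[i, ] != "-" & P[j, ] != "-"
        D[i, j] <- D[j, i] <- if (!any(ok)) 1 else
          mean(P[i, ok] != P[j, ok])
      }
    }
  } else {
    D <- as.matrix(x)
    stopifnot(nrow(D) >= 3L, !is.null(rownames(D)))
  }
  ape::nj(D)
}

#' Root a tree on a fungal outgroup and classify query placements
#'
#' Roots the tree on the fungal outgroup stem and confirms each query as
#' GULO-like iff it attaches inside the ingroup clade spanned by the
#' animal references; queries branching outside that clade (external to
#' the fungi) are flagged non-GULO, mirroring the published treatment of
#' HWGK-bearing sequences that fall outside the fungal outgroup.
#'
#' @param tree A `phylo` tree containing all ids.
#' @param query_ids Tips to classify.
#' @param animal_ref_ids Animal GULO reference tips (>= 2).
#' @param fungal_outgroup_ids Fungal outgroup tips (>= 2).
#' @return Data frame: `id`, `confirmed` (logical).
#' @export
place_and_classify <- function(tree, query_ids, animal_ref_ids,
                               fungal_outgroup_ids) {
  all_ids <- c(query_ids, animal_ref_ids, fungal_outgroup_ids)
  missing <- setdiff(all_ids, tree$tip.label)
  if (length(missing)) stop("ids not in tree: ", paste(missing, collapse = ", "))
  if (length(fungal_outgroup_ids) < 2L) stop("need >= 2 fungal outgroup tips")
  rooted <- tryCatch(
    ape::root(tree, outgroup = fungal_outgroup_ids, resolve.root = TRUE),
    error = function(e)
      ape::root(tree, outgroup = fungal_outgroup_ids[1], resolve.root = TRUE))
  mrca <- ape::getMRCA(rooted, animal_ref_ids)
  below <- .clade_tips(rooted)
  ingroup <- rooted$tip.label[below[[mrca]]]
  data.frame(id = query_ids, confirmed = query_ids %in% ingroup)
}

#' Number of burn-in samples for an MCMC run configuration
#'
#' `floor(generations / sample_every * burnin_frac)`.  With the published
#' run configuration (5,000,000 generations sampled every 100 with 25%
#' burn-in) this is exactly 12,500 discarded samples.
#'
#' @param generations Total MCMC generations.
#' @param sample_every Sampling interval in generations.
#' @param burnin_frac Burn-in fraction in `[0, 1)`.
#' @return Integer number of discarded samples.
#' @export
burnin_count <- function(generations = 5e6, sample_every = 100L,
                         burnin_frac = 0.25) {
  stopifnot(generations >= sample_every, sample_every >= 1,
            burnin_frac >= 0, burnin_frac < 1)
  as.integer(floor(generations / sample_every * burnin_frac))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' PSRF = sqrt((n-1)/n + B/(n*W)) where W is the mean within-chain
#' variance and B the between-chain variance of the chain means (times n).
#' Defined as 1.0 when both variances are zero (identical constant
#' chains).  Values near 1.00 indicate convergence.
#'
#' @param chains A numeric matrix (iterations x chains) or list of >= 2
#'   equal-length numeric vectors of length >= 2.
#' @return The PSRF (a single number).
#' @export
psrf <- function(chains) {
  if (is.list(chains)) {
    lens <- lengths(chains)
    stopifnot(length(chains) >= 2L, length(unique(lens)) == 1L)
    chains <- do.call(cbind, chains)
  }
  stopifnot(is.matrix(chains), ncol(chains) >= 2L, nrow(chains) >= 2L)
  n <- nrow(chains)
  W <- mean(apply(chains, 2, stats::var))
  B <- n * stats::var(colMeans(chains))
  if (W == 0 && B == 0) return(1.0)
  if (W == 0) return(Inf)
  sqrt((n - 1) / n + B / (n * W))
}
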