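# Six-frame translated seeded local-alignment search (tblastn-style) of a
# protein query against nucleotide scaffolds, with flank extraction.

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# 0-based row indices into BLOSUM62 for an amino-acid string
.aa_index <- function(aa) {
  rows <- rownames(.blosum62())
  i <- match(strsplit(aa, "", fixed = TRUE)[[1]], rows)
  i[is.na(i)] <- match("X", rows)
  i - 1L
}

#' Parameters for the translated search
#'
#' Defaults follow the published pipeline where it fixes them: E-value
#' cutoff 0.05, 5000-nt flanks around HSPs, word size 2 for the
#' annotation-guide search.  The discovery word size (3), seed thresholds,
#' gap costs (11/1 on BLOSUM62) and gapped Karlin-Altschul parameters
#' (lambda = 0.267, K = 0.041) are standard values; effective-length
#' corrections are not applied.
#'
#' @param evalue_max Maximum reported E-value.
#' @param word_size Seed word size, 2 or 3.
#' @param flank Nucleotides retrieved on both sides of each HSP.
#' @param gap_open,gap_extend Affine gap costs (gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param x_drop X-drop termination threshold for gapped extension.
#' @param seed_threshold Minimum word score T for a seed; default 11 for
#'   word size 3 and 8 for word size 2.
#' @param karlin_lambda,karlin_k Karlin-Altschul parameters.
#' @return A `search_params` list.
#' @export
search_params <- function(evalue_max = 0.05, word_size = 3L, flank = 5000L,
                          gap_open = 11, gap_extend = 1, x_drop = 20,
                          seed_threshold = NULL,
                          karlin_lambda = 0.267, karlin_k = 0.041) {
  stopifnot(word_size %in% c(2L, 3L), flank >= 0L, evalue_max > 0)
  if (is.null(seed_threshold))
    seed_threshold <- if (word_size == 3L) 11 else 8
  structure(list(evalue_max = evalue_max, word_size = as.integer(word_size),
                 flank = as.integer(flank), gap_open = gap_open,
                 gap_extend = gap_extend, x_drop = x_drop,
                 seed_threshold = seed_threshold,
                 karlin_lambda = karlin_lambda, karlin_k = karlin_k),
            class = "search_params")
}

#' Find seed word hits between a query and one translated frame
#'
#' Reports every (query, target) position pair where the query word of
#' `word_size` residues scores at least the seed threshold T against the
#' translated frame under BLOSUM62; exact-match words are always included
#' regardless of score.
#'
#' @param query Query protein string.
#' @param frame_translation One translated frame (protein string).
#' @param params [search_params()].
#' @return Data frame with 0-based `q_pos`, `t_pos` word start positions.
#' @export
seed_hits <- function(query, frame_translation, params = search_params()) {
  w <- params$word_size
  stopifnot(w <= nchar(query))
  nq <- nchar(query); nt <- nchar(frame_translation)
  empty <- data.frame(q_pos = integer(0), t_pos = integer(0))
  if (nt < w) return(empty)
  M <- .blosum62()
  qi <- .aa_index(query) + 1L
  ti <- .aa_index(frame_translation) + 1L
  nr <- nq - w + 1L; nc <- nt - w + 1L
  S <- matrix(0, nr, nc)
  Eq <- matrix(TRUE, nr, nc)
  for (k in seq_len(w) - 1L) {
    blk <- M[qi[seq_len(nr) + k], ti[seq_len(nc) + k], drop = FALSE]
    S <- S + blk
    Eq <- Eq & (outer(qi[seq_len(nr) + k], ti[seq_len(nc) + k], `==`))
  }
  hit <- which(S >= params$seed_threshold | Eq, arr.ind = TRUE)
  data.frame(q_pos = hit[, 1] - 1L, t_pos = hit[, 2] - 1L)
}

# map aa coordinates in a translated frame back to forward-strand nt coords
.frame_nt_coords <- function(aa_start, aa_end, frame, scaffold_len) {
  off <- abs(frame) - 1L
  if (frame > 0) {
    c(off + 3L * aa_start, off + 3L * aa_end)
  } else {
    c(scaffold_len - (off + 3L * aa_end), scaffold_len - (off + 3L * aa_start))
  }
}

#' Extend one seed into a gapped HSP
#'
#' Gapped local extension in both directions from the seed word with affine
#' gaps and X-drop termination.  Bit score = (lambda*S - ln K)/ln 2 and
#' E-value = K*m*n*exp(-lambda*S) with m the query length in aa and n the
#' total searched nucleotide length / 3.
#'
#' @param seed One row of [seed_hits()] output (`q_pos`, `t_pos`).
#' @param query Query protein string.
#' @param scaffold Scaffold nucleotide string.
#' @param frame Frame in +1..+3, -1..-3.
#' @param params [search_params()].
#' @param n_search Total searched length in aa (defaults to this scaffold's
#'   length / 3).
#' @return One-row data frame: scaffold coords (0-based half-open, forward
#'   strand), query coords (aa), raw/bit scores, evalue, identity_frac.
#' @export
extend_hsp <- function(seed, query, scaffold, frame, params = search_params(),
                       n_search = NULL) {
  tr <- translate_frame(scaffold, frame)
  if (is.null(n_search)) n_search <- nchar(scaffold) / 3
  ext <- cpp_xdrop_extend(.aa_index(query), .aa_index(tr),
                          as.integer(seed$q_pos), as.integer(seed$t_pos),
                          params$word_size, .blosum62(), params$gap_open,
                          params$gap_extend, params$x_drop)
  s <- ext$score
  bit <- (params$karlin_lambda * s - log(params$karlin_k)) / log(2)
  ev <- params$karlin_k * nchar(query) * n_search *
    exp(-params$karlin_lambda * s)
  nt <- .frame_nt_coords(ext$t_start, ext$t_end, frame, nchar(scaffold))
  qseg <- substr(query, ext$q_start + 1L, ext$q_end)
  tseg <- substr(tr, ext$t_start + 1L, ext$t_end)
  idf <- if (nchar(qseg) == 0 || nchar(tseg) == 0) 0 else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(qseg), Biostrings::AAString(tseg),
      type = "global", substitutionMatrix = .blosum62(),
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    Biostrings::pid(pa) / 100
  }
  data.frame(frame = frame, q_start = ext$q_start, q_end = ext$q_end,
             s_start = nt[1], s_end = nt[2], raw_score = s, bit_score = bit,
             evalue = ev, identity_frac = idf)
}

#' Search a genome with a protein query (tblastn-style)
#'
#' Runs the seeded gapped search over all six frames of every scaffold,
#' keeps HSPs with E-value at or below `params$evalue_max`, removes HSPs
#' contained within a higher-scoring HSP on the same scaffold and frame,
#' and sorts by bit score (descending).
#'
#' @param query Query protein string (non-empty).
#' @param scaffolds Named nucleotide vector.
#' @param params [search_params()].
#' @return Data frame of HSPs with columns `hsp_id`, `scaffold_id`,
#'   `frame`, `q_start`, `q_end`, `s_start`, `s_end`, `raw_score`,
#'   `bit_score`, `evalue`, `identity_frac`.
#' @export
search_genome <- function(query, scaffolds, params = search_params()) {
  if (nchar(query) == 0L) stop("empty query")
  stopifnot(length(scaffolds) > 0L)
  n_search <- sum(nchar(scaffolds)) / 3
  out <- list()
  for (sc in names(scaffolds)) {
    sseq <- scaffolds[[sc]]
    slen <- nchar(sseq)
    qidx <- .aa_index(query)
    for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      tr <- translate_frame(sseq, frame)
      if (nchar(tr) < params$word_size) next
      seeds <- seed_hits(query, tr, params)
      if (nrow(seeds) == 0L) next
      tidx <- .aa_index(tr)
      hsps <- list()
      # a seed is redundant only if an extension seeded on the SAME
      # diagonal already covered it (box-level skipping can starve the
      # optimal diagonal)
      covered <- new.env(parent = emptyenv())
      for (i in seq_len(nrow(seeds))) {
        qp <- seeds$q_pos[i]; tp <- seeds$t_pos[i]
        key <- as.character(tp - qp)
        spans <- get0(key, envir = covered, ifnotfound = NULL)
        if (!is.null(spans) && any(tp >= spans[, 1] & tp < spans[, 2])) next
        ext <- cpp_xdrop_extend(qidx, tidx, qp, tp, params$word_size,
                                .blosum62(), params$gap_open,
                                params$gap_extend, params$x_drop)
        assign(key, rbind(spans, c(ext$t_start, ext$t_end)), envir = covered)
        hsps[[length(hsps) + 1L]] <-
          list(aq0 = ext$q_start, aq1 = ext$q_end, at0 = ext$t_start,
               at1 = ext$t_end, score = ext$score)
      }
      for (h in hsps) {
        s <- h$score
        ev <- params$karlin_k * nchar(query) * n_search *
          exp(-params$karlin_lambda * s)
        if (ev > params$evalue_max) next
        bit <- (params$karlin_lambda * s - log(params$karlin_k)) / log(2)
        nt <- .frame_nt_coords(h$at0, h$at1, frame, slen)
        qseg <- substr(query, h$aq0 + 1L, h$aq1)
        tseg <- substr(tr, h$at0 + 1L, h$at1)
        idf <- if (nchar(qseg) == 0 || nchar(tseg) == 0) 0 else {
          pa <- Biostrings::pairwiseAlignment(
            Biostrings::AAString(qseg), Biostrings::AAString(tseg),
            type = "global", substitutionMatrix = .blosum62(),
            gapOpening = params$gap_open, gapExtension = params$gap_extend)
          Biostrings::pid(pa) / 100
        }
        out[[length(out) + 1L]] <- data.frame(
          scaffold_id = sc, frame = frame, q_start = h$aq0, q_end = h$aq1,
          s_start = nt[1], s_end = nt[2], raw_score = s, bit_score = bit,
          evalue = ev, identity_frac = idf)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(hsp_id = character(0), scaffold_id = character(0),
                      frame = integer(0), q_start = integer(0),
                      q_end = integer(0), s_start = integer(0),
                      s_end = integer(0), raw_score = numeric(0),
                      bit_score = numeric(0), evalue = numeric(0),
                      identity_frac = numeric(0)))
  }
  res <- do.call(rbind, out)
  # drop HSPs fully contained in a higher-scoring HSP on same scaffold+frame
  res <- res[order(-res$raw_score), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(res))) {
      if (j <= i || !keep[j]) next
      if (res$scaffold_id[j] == res$scaffold_id[i] &&
          res$frame[j] == res$frame[i] &&
          res$q_start[j] >= res$q_start[i] && res$q_end[j] <= res$q_end[i] &&
          res$s_start[j] >= res$s_start[i] && res$s_end[j] <= res$s_end[i]) {
        keep[j] <- FALSE
      }
    }
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(-res$bit_score), , drop = FALSE]
  rownames(res) <- NULL
  cbind(hsp_id = paste0("hsp_", seq_len(nrow(res))), res,
        stringsAsFactors = FALSE)
}

#' Extract flank-extended genomic regions around HSPs
#'
#' Retrieves `flank` nucleotides on both sides of each HSP (clipped to the
#' scaffold bounds) and merges regions on the same scaffold whose
#' coordinates overlap, recording the contributing HSP ids.
#'
#' @param hsps Data frame from [search_genome()].
#' @param scaffolds Named nucleotide vector the HSPs refer to.
#' @param flank Flank size in nt (the published pipeline used 5000).
#' @return List of `genomic_region` lists: `region_id`, `scaffold_id`,
#'   `start`, `end` (0-based half-open), `sequence`, `origin_hsp_ids`.
#' @export
extract_flanked_regions <- function(hsps, scaffolds, flank = 5000L) {
  if (nrow(hsps) == 0L) return(list())
  missing <- setdiff(unique(hsps$scaffold_id), names(scaffolds))
  if (length(missing)) stop("HSPs reference unknown scaffolds: ",
                            paste(missing, collapse = ", "))
  regions <- list()
  for (sc in unique(hsps$scaffold_id)) {
    h <- hsps[hsps$scaffold_id == sc, , drop = FALSE]
    slen <- nchar(scaffolds[[sc]])
    st <- pmax(0L, h$s_start - flank)
    en <- pmin(slen, h$s_end + flank)
    o <- order(st)
    st <- st[o]; en <- en[o]; ids <- h$hsp_id[o]
    cur_s <- st[1]; cur_e <- en[1]; cur_ids <- ids[1]
    flush <- function(s, e, idv) {
      regions[[length(regions) + 1L]] <<- list(
        region_id = paste0("region_", length(regions) + 1L),
        scaffold_id = sc, start = s, end = e,
        sequence = substr(scaffolds[[sc]], s + 1L, e),
        origin_hsp_ids = idv)
    }
    for (i in seq_along(st)[-1]) {
      if (st[i] <= cur_e) {
        cur_e <- max(cur_e, en[i])
        cur_ids <- c(cur_ids, ids[i])
      } else {
        flush(cur_s, cur_e, cur_ids)
        cur_s <- st[i]; cur_e <- en[i]; cur_ids <- ids[i]
      }
    }
    flush(cur_s, cur_e, cur_ids)
  }
  regions
}
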