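# "Grow sequences": merge retrieved regions sharing a long exact overlap
# into longer contiguous regions before annotation.

# longest prefix of b that is also a suffix of a (KMP prefix function)
.suffix_prefix_len <- function(a, b) {
  s <- strsplit(paste0(b, "\1", a), "", fixed = TRUE)[[1]]
  n <- length(s)
  pi_ <- integer(n)
  k <- 0L
  for (i in 2:n) {
    while (k > 0L && s[k + 1L] != s[i]) k <- pi_[k]
    if (s[k + 1L] == s[i]) k <- k + 1L
    pi_[i] <- k
  }
  min(pi_[n], nchar(a), nchar(b))
}

#' Find an exact overlap between two sequences
#'
#' Detects the longest exact suffix/prefix overlap of length at least
#' `min_overlap` in either orientation-free order, or full containment of
#' one sequence in the other.
#'
#' @param a,b Nucleotide strings.
#' @param min_overlap Minimum overlap length in nt (the published pipeline
#'   used 2500).
#' @return `NULL` if no qualifying overlap, else a list with `type`
#'   (`"a_then_b"`, `"b_then_a"`, `"a_contains_b"`, `"b_contains_a"`) and
#'   `length` (overlap length).
#' @export
find_overlap <- function(a, b, min_overlap = 2500L) {
  stopifnot(min_overlap >= 1L)
  if (nchar(b) <= nchar(a) && grepl(b, a, fixed = TRUE))
    return(list(type = "a_contains_b", length = nchar(b)))
  if (nchar(a) < nchar(b) && grepl(a, b, fixed = TRUE))
    return(list(type = "b_contains_a", length = nchar(a)))
  ab <- .suffix_prefix_len(a, b)
  ba <- .suffix_prefix_len(b, a)
  if (max(ab, ba) < min_overlap) return(NULL)
  if (ab >= ba) list(type = "a_then_b", length = ab)
  else list(type = "b_then_a", length = ba)
}

.merge_pair <- function(ra, rb, ov) {
  seq <- switch(ov$type,
    a_then_b = paste0(ra$sequence,
                      substr(rb$sequence, ov$length + 1L, nchar(rb$sequence))),
    b_then_a = paste0(rb$sequence,
                      substr(ra$sequence, ov$length + 1L, nchar(ra$sequence))),
    a_contains_b = ra$sequence,
    b_contains_a = rb$sequence)
  ids <- sort(c(ra$region_id, rb$region_id))
  scafs <- unique(c(ra$scaffold_id, rb$scaffold_id))
  single <- length(scafs) == 1L
  list(region_id = ids[1], scaffold_id = scafs,
       start = if (single) min(ra$start, rb$start) else NA_integer_,
       end = if (single) max(ra$end, rb$end) else NA_integer_,
       sequence = seq,
       origin_hsp_ids = sort(unique(c(ra$origin_hsp_ids, rb$origin_hsp_ids))))
}

#' Grow overlapping regions into longer contiguous regions
#'
#' Iterated pairwise merging until fixpoint: at each step the pair with the
#' longest qualifying overlap (ties broken by lexicographic region id) is
#' merged; the merged sequence has length `|a| + |b| - overlap` and the
#' union of the contributing HSP ids.
#'
#' @param regions List of `genomic_region` lists (see
#'   [extract_flanked_regions()]).
#' @param min_overlap Minimum exact overlap in nt (default 2500).
#' @return The grown region list, in canonical (region id) order.
#' @export
grow_sequences <- function(regions, min_overlap = 2500L) {
  regs <- regions[order(vapply(regions, `[[`, character(1), "region_id"))]
  repeat {
    n <- length(regs)
    if (n < 2L) break
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ov <- find_overlap(regs[[i]]$sequence, regs[[j]]$sequence, min_overlap)
        if (!is.null(ov) &&
            (is.null(best) || ov$length > best$ov$length)) {
          best <- list(i = i, j = j, ov = ov)
        }
      }
    }
    if (is.null(best)) break
    merged <- .merge_pair(regs[[best$i]], regs[[best$j]], best$ov)
    regs <- c(regs[-c(best$i, best$j)], list(merged))
    regs <- regs[order(vapply(regs, `[[`, character(1), "region_id"))]
  }
  regs
}
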