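#' @useDynLib gulotrace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

# Sequences travel as named character vectors: names are record ids, values
# are uppercase residue strings.  All internal coordinates are 0-based,
# half-open; GFF3 output converts to 1-based inclusive.

.NUC_ALPHABET <- c("A", "C", "G", "T", "N")
.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "W", "Y", "V", "T", "X", "*")

#' Parse FASTA text into a set of sequences
#'
#' Accepts multi-record FASTA with arbitrary line wrapping.  Residues are
#' concatenated and uppercased; any character outside the declared alphabet
#' is a parse error that names the offending record and 1-based residue
#' position.
#'
#' @param text A single string of FASTA text, or a character vector of lines.
#' @param alphabet `"dna"` (A/C/G/T/N), `"protein"` (20 amino acids plus X
#'   and `*`), or `"auto"` to guess per record.
#' @return Named character vector of uppercase residue strings (names = ids).
#'   Empty input yields an empty vector.
#' @examples
#' parse_fasta(">a\nac\ngt\n>b\nTTTT", alphabet = "dna")
#' @export
parse_fasta <- function(text, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) stop("FASTA input must start with a '>' header line")
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  if (any(!nzchar(ids))) stop("FASTA record with empty id")
  if (anyDuplicated(ids)) stop("duplicate FASTA ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  res <- vapply(split(lines[!hdr], factor(rec[!hdr], levels = seq_along(ids))),
                function(x) toupper(paste(x, collapse = "")), character(1))
  names(res) <- ids
  for (i in seq_along(res)) {
    ab <- if (alphabet == "auto") {
      if (grepl("^[ACGTN]*$", res[[i]])) "dna" else "protein"
    } else alphabet
    .check_alphabet(res[[i]], ab, ids[i])
  }
  res
}

.check_alphabet <- function(residues, alphabet, id) {
  ok <- if (alphabet == "dna") .NUC_ALPHABET else .AA_ALPHABET
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% ok)
  if (length(bad)) {
    stop(sprintf("record '%s': invalid %s character '%s' at position %d",
                 id, alphabet, chars[bad[1]], bad[1]))
  }
  invisible(TRUE)
}

#' Write sequences as FASTA text
#'
#' @param seqs Named character vector of residue strings.
#' @param path Optional file path; if `NULL` the FASTA text is returned.
#' @param width Line-wrap width.
#' @return The FASTA text (invisibly when written to a file).
#' @export
write_fasta <- function(seqs, path = NULL, width = 70L) {
  out <- unlist(lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    body <- if (nchar(s) == 0L) character(0) else {
      starts <- seq(1L, nchar(s), by = width)
      substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    }
    c(paste0(">", names(seqs)[i]), body)
  }))
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(txt))
  }
  txt
}

#' Reverse complement of a nucleotide string
#'
#' @param x Nucleotide string over A/C/G/T/N.
#' @return The reverse complement string.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

# codon -> amino acid table (standard code), derived from Biostrings
.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

#' Translate a nucleotide sequence in a given reading frame
#'
#' Standard genetic code.  Negative frames translate the reverse complement.
#' Codons containing N translate to X; stop codons yield `*`; a trailing
#' partial codon is dropped.
#'
#' @param x Nucleotide string.
#' @param frame One of +1, +2, +3, -1, -2, -3.
#' @return Amino-acid string (possibly empty).
#' @examples
#' translate_frame("ATGCATTGGGCTAAA", 1)  # "MHWAK"
#' @export
translate_frame <- function(x, frame = 1L) {
  stopifnot(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
  if (frame < 0) x <- revcomp(x)
  off <- abs(frame) - 1L
  n <- nchar(x) - off
  if (n < 3L) return("")
  n_codons <- n %/% 3L
  starts <- off + 1L + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(x, starts, starts + 2L)
  tab <- .codon_table()
  aa <- tab[codons]
  aa[is.na(aa)] <- "X"  # codons containing N (or other ambiguity)
  paste(aa, collapse = "")
}

#' Parse a Newick tree string
#'
#' Thin wrapper over [ape::read.tree()] adding the validity checks the
#' pipeline relies on: a single tree, unique leaf labels, balanced syntax.
#'
#' @param text Newick string terminated by `;`.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick string")
  if (inherits(tr, "multiPhylo")) stop("expected a single Newick tree")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Serialise a tree to Newick
#'
#' @param tree A `phylo` object.
#' @return Newick string (with trailing `;`).
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/CDS features with 1-based inclusive coordinates and CDS
#' phase computed from cumulative coding length, converting from the
#' package's internal 0-based half-open convention.
#'
#' @param models List of gene models (as returned by [chain_exons()] or
#'   planted by [synth_genome()]), each with fields `gene_id`,
#'   `scaffold_id`, `strand`, and `exons` (data frame with 0-based
#'   half-open `start`, `end`, ordered in transcription order).
#' @param path Optional output file.
#' @return Character vector of GFF3 lines (invisibly when written).
#' @export
write_gff3 <- function(models, path = NULL) {
  lines <- "##gff-version 3"
  for (m in models) {
    ex <- m$exons
    gstart <- min(ex$start) + 1L
    gend <- max(ex$end)
    gid <- m$gene_id
    lines <- c(lines,
      paste(m$scaffold_id, "gulotrace", "gene", gstart, gend, ".", m$strand,
            ".", sprintf("ID=%s", gid), sep = "\t"),
      paste(m$scaffold_id, "gulotrace", "mRNA", gstart, gend, ".", m$strand,
            ".", sprintf("ID=%s.t1;Parent=%s", gid, gid), sep = "\t"))
    cum <- 0L
    for (i in seq_len(nrow(ex))) {
      phase <- (3L - cum %% 3L) %% 3L
      lines <- c(lines,
        paste(m$scaffold_id, "gulotrace", "CDS", ex$start[i] + 1L, ex$end[i],
              ".", m$strand, phase,
              sprintf("ID=%s.cds;Parent=%s.t1", gid, gid), sep = "\t"))
      cum <- cum + (ex$end[i] - ex$start[i])
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
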