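# DNA sequences, IUPAC degeneracy, reverse complement, FASTA I/O.

# IUPAC nucleotide degeneracy sets. N is a valid *pattern* code but a
# sequence N matches nothing (conservative handling of masked regions).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Construct a DNA sequence record
#'
#' A light container for a single DNA sequence: an identifier, the bases
#' (uppercase, `A`/`C`/`G`/`T`/`N` only) and an integer offset giving the
#' coordinate of the first base. The offset is used only when reporting
#' positions in promoter coordinates (for example an offset of -1800 for a
#' promoter fragment cloned from -1800 relative to the transcription start
#' site); all internal coordinates are 0-based half-open on the plus strand.
#'
#' @param bases Character scalar of bases. Lowercase input is accepted and
#'   upper-cased. Degeneracy codes other than `N` are rejected: they belong
#'   in patterns (see [consensus_pattern()]), not in sequences.
#' @param id Label for the sequence.
#' @param offset Integer coordinate of the first base (default 0).
#' @return An object of class `dna_sequence`.
#' @examples
#' p53 <- dna_sequence("AAATATTTATTATCGA", id = "p53-DNA")
#' reverse_complement(p53)
#' @export
dna_sequence <- function(bases, id = "seq", offset = 0L) {
  if (!is.character(bases) || length(bases) != 1L || is.na(bases)) {
    abort("`bases` must be a single character string.")
  }
  bases <- toupper(bases)
  if (!nzchar(bases)) abort("`bases` must be non-empty.")
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    abort(sprintf(
      "Invalid base '%s' at position %d (1-based); sequences may contain only A, C, G, T, N.",
      chars[bad[1]], bad[1]
    ))
  }
  structure(
    list(id = as.character(id), bases = bases, offset = as.integer(offset)),
    class = "dna_sequence"
  )
}

#' @export
print.dna_sequence <- function(x, ...) {
  cat(sprintf(
    "<dna_sequence> %s (%d nt, offset %d)\n%s\n",
    x$id, nchar(x$bases), x$offset,
    if (nchar(x$bases) > 60) paste0(substr(x$bases, 1, 57), "...") else x$bases
  ))
  invisible(x)
}

as_dna <- function(x, id = "seq") {
  if (inherits(x, "dna_sequence")) x else dna_sequence(x, id = id)
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement of the reversed base string. Applying it twice
#' returns the input. Works on `dna_sequence` objects or bare strings (a
#' string in gives a string out).
#'
#' @param seq A [dna_sequence()] or a character scalar.
#' @return Same type as the input.
#' @examples
#' reverse_complement("AAATATTTATTATCGA") # "TCGATAATAAATATTT"
#' @export
reverse_complement <- function(seq) {
  string_in <- !inherits(seq, "dna_sequence")
  s <- as_dna(seq)
  chars <- strsplit(s$bases, "", fixed = TRUE)[[1]]
  rc <- paste(rev(unname(COMPLEMENT[chars])), collapse = "")
  if (string_in) return(rc)
  dna_sequence(rc, id = paste0(s$id, "_rc"), offset = s$offset)
}

#' Define an IUPAC consensus pattern
#'
#' A degenerate nucleotide pattern such as the canonical FOX-binding element
#' `RYAAAYA` (`R` = A/G, `Y` = C/T). Every character must be a valid IUPAC
#' nucleotide code and the pattern must be at least 4 long.
#'
#' @param pattern Character scalar over IUPAC codes.
#' @param name Label used in scan output (defaults to the pattern itself).
#' @return An object of class `consensus_pattern`.
#' @examples
#' fbe <- consensus_pattern("RYAAAYA", name = "FBE")
#' @export
consensus_pattern <- function(pattern, name = pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern)) {
    abort("`pattern` must be a single character string.")
  }
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad) > 0L) {
    abort(sprintf("Invalid IUPAC code '%s' at position %d.", chars[bad[1]], bad[1]))
  }
  if (length(chars) < 4L) abort("Patterns must be at least 4 nucleotides long.")
  structure(list(pattern = pattern, name = as.character(name)),
            class = "consensus_pattern")
}

as_pattern <- function(x) {
  if (inherits(x, "consensus_pattern")) x else consensus_pattern(x)
}

#' Test a site against an IUPAC consensus pattern
#'
#' `TRUE` iff every base of `site` lies in the degeneracy set of the
#' corresponding pattern position. An `N` in the site matches nothing.
#'
#' @param site Character scalar of bases, same length as the pattern.
#' @param pattern A [consensus_pattern()] or pattern string.
#' @return Logical scalar.
#' @examples
#' iupac_matches("ATAAATA", "RYAAAYA") # TRUE
#' iupac_matches("GTAAACA", "RYAAAYA") # TRUE
#' @export
iupac_matches <- function(site, pattern) {
  pattern <- as_pattern(pattern)
  site <- toupper(site)
  if (nchar(site) != nchar(pattern$pattern)) {
    abort(sprintf("Site length (%d) does not match pattern length (%d).",
                  nchar(site), nchar(pattern$pattern)))
  }
  sc <- strsplit(site, "", fixed = TRUE)[[1]]
  pc <- strsplit(pattern$pattern, "", fixed = TRUE)[[1]]
  if (any(sc == "N")) return(FALSE)
  all(vapply(seq_along(sc), function(i) sc[i] %in% IUPAC_SETS[[pc[i]]], logical(1)))
}

#' Read DNA sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a list of
#' [dna_sequence()] objects. Multi-record files and wrapped lines are
#' handled by Biostrings.
#'
#' @param path Path to a FASTA file.
#' @param offset Integer offset applied to every record (default 0).
#' @return Named list of `dna_sequence` objects.
#' @export
read_fasta <- function(path, offset = 0L) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    dna_sequence(as.character(set[[i]]), id = names(set)[i] %||% paste0("seq", i),
                 offset = offset)
  })
  names(out) <- vapply(out, function(s) s$id, character(1))
  out
}
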