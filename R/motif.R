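# Strand-aware consensus scanning and homotypic site-pair annotation.

#' Scan a sequence for an IUPAC consensus pattern
#'
#' Tests every window of the sequence against the pattern on the plus strand
#' and, if `both_strands`, against the reverse complement of the window for
#' minus-strand hits. All coordinates are 0-based half-open on the plus
#' strand; the `site` column is always the plus-strand slice, so a
#' minus-strand hit satisfies `iupac_matches(reverse_complement(site),
#' pattern)`. Overlapping hits are all reported.
#'
#' @param seq A [dna_sequence()] or character scalar.
#' @param pattern A [consensus_pattern()] or pattern string.
#' @param both_strands Scan the minus strand too? Default `TRUE`.
#' @return A tibble with columns `seq_id`, `start`, `end`, `strand`, `site`,
#'   `pattern`, plus `promoter_start`/`promoter_end` (coordinates shifted by
#'   the sequence offset). Sorted by `start`, plus strand before minus at
#'   equal start.
#' @examples
#' scan_motif("AAATATTTATTATCGA", "RYAAAYA")
#' @export
scan_motif <- function(seq, pattern, both_strands = TRUE) {
  seq <- as_dna(seq)
  pattern <- as_pattern(pattern)
  L <- nchar(seq$bases)
  w <- nchar(pattern$pattern)
  if (w > L) abort("Pattern is longer than the sequence.")

  starts <- 0:(L - w)
  windows <- vapply(starts, function(s) substr(seq$bases, s + 1L, s + w), character(1))
  plus <- vapply(windows, iupac_matches, logical(1), pattern = pattern)
  hits <- tibble(start = starts[plus], strand = "+", site = windows[plus])
  if (isTRUE(both_strands)) {
    minus <- vapply(windows, function(x) iupac_matches(reverse_complement(x), pattern),
                    logical(1))
    hits <- dplyr::bind_rows(
      hits,
      tibble(start = starts[minus], strand = "-", site = windows[minus])
    )
  }
  hits |>
    dplyr::mutate(
      seq_id = seq$id,
      end = .data$start + w,
      pattern = pattern$name,
      promoter_start = .data$start + seq$offset,
      promoter_end = .data$end + seq$offset
    ) |>
    dplyr::arrange(.data$start, .data$strand) |>
    dplyr::select("seq_id", "start", "end", "strand", "site", "pattern",
                  "promoter_start", "promoter_end")
}

#' Annotate homotypic site pairs (primary site + adjacent secondary site)
#'
#' Given primary-pattern matches on a sequence, finds secondary-pattern hits
#' lying adjacent to each primary hit and reports the pairs. Adjacency is
#' expressed through the signed `overlap` column: positive values are
#' overlapping bases, negative values are gap sizes. A pair is kept when its
#' overlap is at most `max_overlap` bases and its gap is at most `max_gap`
#' bases. The two-site architecture on the TP53 promoter probe (FBE1 at
#' `[3,10)` and FBE2 `ATTATCG` at `[8,15)` of the printed 16-mer) is a
#' 2-base-overlap pair.
#'
#' @param matches Tibble of primary matches from [scan_motif()] (one
#'   sequence only).
#' @param secondary A [consensus_pattern()] or string for the secondary site.
#' @param seq The sequence the matches came from.
#' @param max_overlap Maximum allowed overlapping bases (default 2).
#' @param max_gap Maximum allowed gap in bases (default 0).
#' @return Tibble with one row per (primary, secondary) pair: primary and
#'   secondary coordinates/strands/sites, `pair_id` and signed `overlap`.
#'   Empty tibble when no pairs qualify.
#' @export
annotate_homotypic_pairs <- function(matches, secondary, seq,
                                     max_overlap = 2L, max_gap = 0L) {
  seq <- as_dna(seq)
  secondary <- as_pattern(secondary)
  if (nrow(matches) > 0 && length(unique(matches$seq_id)) > 1L) {
    abort("`matches` must all come from the same sequence.")
  }
  empty <- tibble(
    pair_id = integer(), seq_id = character(),
    primary_start = integer(), primary_end = integer(),
    primary_strand = character(), primary_site = character(),
    secondary_start = integer(), secondary_end = integer(),
    secondary_strand = character(), secondary_site = character(),
    overlap = integer()
  )
  if (nrow(matches) == 0L) return(empty)

  sec_hits <- scan_motif(seq, secondary, both_strands = TRUE)
  if (nrow(sec_hits) == 0L) return(empty)

  pairs <- tidyr::crossing(
    matches |>
      dplyr::select(seq_id = "seq_id", primary_start = "start",
                    primary_end = "end", primary_strand = "strand",
                    primary_site = "site"),
    sec_hits |>
      dplyr::select(secondary_start = "start", secondary_end = "end",
                    secondary_strand = "strand", secondary_site = "site")
  ) |>
    # drop the degenerate pairing of a site with itself
    dplyr::filter(!(.data$secondary_start == .data$primary_start &
                      .data$secondary_end == .data$primary_end)) |>
    dplyr::mutate(
      overlap = pmin(.data$primary_end, .data$secondary_end) -
        pmax(.data$primary_start, .data$secondary_start)
    ) |>
    dplyr::filter(.data$overlap <= max_overlap, -.data$overlap <= max_gap) |>
    dplyr::arrange(.data$primary_start, .data$secondary_start) |>
    dplyr::mutate(pair_id = dplyr::row_number(), .before = 1)
  if (nrow(pairs) == 0L) empty else pairs
}
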