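# DNA minor-groove-width geometry from atomic structures, and an ideal
# fiber-model B-DNA backbone generator used as the reference profile.
#
# Width convention: for each phosphate on the reference strand, the minimum
# cross-minor-groove P-P distance to the partner strand (register offsets
# i-5 ... i-1 relative to the Watson-Crick partner level), minus 5.8 A for
# the two phosphate-group radii.

#' Generate an ideal fiber-model B-DNA phosphate backbone
#'
#' Places backbone phosphorus atoms on two antiparallel helices in
#' cylindrical coordinates: radius 8.91 A, helical twist 36 degrees per base
#' pair, rise 3.38 A per base pair, and a 144 degree inter-strand phase
#' angle between the two phosphates of a base-pair level. The 5' residue of
#' each strand carries no phosphate, so an `n_bp` duplex has `n_bp - 1` P
#' atoms per strand. Deterministic.
#'
#' @param n_bp Number of base pairs (>= 8 so that interior levels remain
#'   after terminal exclusion).
#' @param seq Optional [dna_sequence()] of length `n_bp` used for residue
#'   names; defaults to alternating A/T.
#' @param radius,twist,rise,phase Helical parameters (A, degrees, A,
#'   degrees).
#' @return Object of class `nucleic_structure`: tibble `atoms` with columns
#'   `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`, plus `chain_pair`
#'   and `n_levels`. Chain A runs 5'->3' with level = residue number; chain
#'   B is antiparallel (its residue `b` sits at level `n_bp + 1 - b`).
#' @examples
#' bdna <- make_fiber_bdna(16)
#' minor_groove_widths(bdna)
#' @export
make_fiber_bdna <- function(n_bp, seq = NULL, radius = 8.91, twist = 36,
                            rise = 3.38, phase = 144) {
  if (n_bp < 8) abort("`n_bp` must be >= 8 (too few interior levels otherwise).")
  bases <- if (!is.null(seq)) {
    seq <- as_dna(seq)
    if (nchar(seq$bases) != n_bp) abort("`seq` length must equal `n_bp`.")
    strsplit(seq$bases, "", fixed = TRUE)[[1]]
  } else {
    rep(c("A", "T"), length.out = n_bp)
  }
  comp <- unname(COMPLEMENT[bases])
  deg <- pi / 180

  # chain A: residues 2..n carry P at the residue's level
  lev_a <- 2:n_bp
  a <- tibble(
    chain = "A", resno = lev_a, resid = paste0("D", bases[lev_a]), elety = "P",
    x = radius * cos((lev_a - 1) * twist * deg),
    y = radius * sin((lev_a - 1) * twist * deg),
    z = (lev_a - 1) * rise
  )
  # chain B: residue b (5'->3') sits at level n+1-b; residues 2..n carry P
  res_b <- 2:n_bp
  lev_b <- n_bp + 1 - res_b
  b <- tibble(
    chain = "B", resno = res_b, resid = paste0("D", comp[lev_b]), elety = "P",
    x = radius * cos(((lev_b - 1) * twist + phase) * deg),
    y = radius * sin(((lev_b - 1) * twist + phase) * deg),
    z = (lev_b - 1) * rise
  )
  structure(
    list(atoms = dplyr::bind_rows(a, b), chain_pair = c("A", "B"),
         n_levels = as.integer(n_bp)),
    class = "nucleic_structure"
  )
}

#' @export
print.nucleic_structure <- function(x, ...) {
  cat(sprintf(
    "<nucleic_structure> chains %s/%s, %d base-pair levels, %d P atoms\n",
    x$chain_pair[1], x$chain_pair[2], x$n_levels, nrow(x$atoms)
  ))
  invisible(x)
}

DNA_RESIDUES <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "T", "U")

#' Write a nucleic-acid structure to a PDB file
#'
#' Emits standard ATOM records via [bio3d::write.pdb()] (occupancy 1.00,
#' B-factor 0.00).
#'
#' @param struct A `nucleic_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(struct, path) {
  stopifnot(inherits(struct, "nucleic_structure"))
  at <- struct$atoms
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resno, resid = at$resid, chain = at$chain,
    eleno = seq_len(nrow(at)), elety = at$elety,
    o = rep(1, nrow(at)), b = rep(0, nrow(at)), elesy = rep("P", nrow(at))
  )
  invisible(path)
}

#' Read a nucleic-acid duplex from a PDB file
#'
#' Parses the file with [bio3d::read.pdb()], keeps phosphorus (`P`) atoms of
#' nucleotide residues, auto-detects DNA chains by residue name
#' (`DA`/`DC`/`DG`/`DT`/...) when `chain_pair` is not given, and assigns
#' antiparallel base-pair levels: the first chain's residues are numbered
#' 5'->3' as levels `1..n`, the partner chain's residue `b` is assigned
#' level `n + 1 - b` (matched antiparallel numbering, the layout written by
#' [write_structure_pdb()] and typical of duplex PDB entries). Protein
#' chains are ignored.
#'
#' @param path Path to a PDB-format file.
#' @param chain_pair Optional two chain ids (reference strand first).
#' @return A `nucleic_structure`.
#' @export
read_structure <- function(path, chain_pair = NULL) {
  if (!file.exists(path)) abort(sprintf("PDB file not found: %s", path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) abort(sprintf("Cannot parse PDB file: %s", conditionMessage(e))))
  at <- as_tibble(pdb$atom)
  nuc <- at |>
    dplyr::filter(toupper(.data$resid) %in% DNA_RESIDUES, .data$elety == "P")
  if (is.null(chain_pair)) {
    chain_pair <- unique(nuc$chain)
    if (length(chain_pair) != 2L) {
      abort(sprintf(
        "Expected exactly 2 DNA chains with phosphates, found %d (%s); pass `chain_pair`.",
        length(chain_pair), paste(chain_pair, collapse = ", ")
      ))
    }
  }
  for (ch in chain_pair) {
    n_p <- sum(nuc$chain == ch)
    if (n_p == 0) abort(sprintf("No nucleotide phosphates in chain %s.", ch))
    if (n_p < 6) abort(sprintf("Chain %s has only %d phosphates (>= 6 required).", ch, n_p))
  }
  nuc <- nuc |>
    dplyr::filter(.data$chain %in% chain_pair) |>
    dplyr::arrange(match(.data$chain, chain_pair), .data$resno) |>
    dplyr::select("chain", "resno", "resid", "elety", "x", "y", "z")
  # renumber each chain's phosphate residues from 2 upward: the 5' residue
  # of a strand carries no phosphate, so the first P belongs to residue 2
  nuc <- nuc |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(resno = .data$resno - min(.data$resno) + 2L) |>
    dplyr::ungroup()
  structure(
    list(atoms = nuc, chain_pair = chain_pair,
         n_levels = as.integer(max(nuc$resno))),
    class = "nucleic_structure"
  )
}

# phosphate coordinates by base-pair level for one strand of a structure
phosphate_levels <- function(struct, which_chain) {
  at <- struct$atoms |> dplyr::filter(.data$chain == which_chain)
  n <- struct$n_levels
  if (which_chain == struct$chain_pair[1]) {
    at |> dplyr::mutate(level = .data$resno)
  } else {
    at |> dplyr::mutate(level = n + 1L - .data$resno)
  }
}

#' Per-level minor groove widths of a DNA duplex
#'
#' For each phosphate on the reference strand (excluding `exclude_terminal`
#' levels at each end of the profile), the width is the minimum P-P distance
#' to partner-strand phosphates at cross-minor-groove register offsets
#' (default levels `i-5 ... i-1` relative to the Watson-Crick partner
#' level), minus `vdw_correction` (default 5.8 A, the standard convention
#' for the two phosphate radii). Levels whose partner phosphates are all
#' missing (crystallographic disorder) are dropped, not interpolated.
#'
#' @param struct A `nucleic_structure`.
#' @param offsets Integer vector of partner-level offsets (default `-5:-1`).
#' @param vdw_correction Subtracted from the raw P-P distance (A).
#' @param exclude_terminal Levels dropped at each profile end (default 2).
#' @return Tibble (`groove_profile`): `level`, `ref_res`, `partner_res`,
#'   `pp_dist_A`, `width_A`, ordered 5'->3' on the reference strand.
#' @export
minor_groove_widths <- function(struct, offsets = -5:-1, vdw_correction = 5.8,
                                exclude_terminal = 2) {
  stopifnot(inherits(struct, "nucleic_structure"))
  ref <- phosphate_levels(struct, struct$chain_pair[1])
  prt <- phosphate_levels(struct, struct$chain_pair[2])
  if (nrow(ref) < 2 * exclude_terminal + 1) abort("Too few reference phosphates.")

  lv <- sort(ref$level)
  keep <- lv[(exclude_terminal + 1):(length(lv) - exclude_terminal)]
  if (length(keep) < 1) abort("Too few levels after terminal exclusion.")

  rows <- purrr::map(keep, function(i) {
    r <- ref[ref$level == i, ]
    cand <- prt[prt$level %in% (i + offsets), ]
    if (nrow(r) != 1L || nrow(cand) == 0L) return(NULL)
    d <- sqrt((cand$x - r$x)^2 + (cand$y - r$y)^2 + (cand$z - r$z)^2)
    j <- which.min(d)
    tibble(level = i, ref_res = r$resno, partner_res = cand$resno[j],
           pp_dist_A = d[j], width_A = d[j] - vdw_correction)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) abort("No measurable levels: partner phosphates missing.")
  class(out) <- c("groove_profile", class(out))
  out
}

#' Summarise a groove profile
#'
#' @param profile Tibble from [minor_groove_widths()].
#' @return Tibble with `min`, `mean`, `max` width (A) and `n_levels`.
#' @export
groove_summary <- function(profile) {
  tibble(min = min(profile$width_A), mean = mean(profile$width_A),
         max = max(profile$width_A), n_levels = nrow(profile))
}

#' Compare two groove profiles level by level
#'
#' Aligns two profiles on their shared levels and reports the per-level
#' width difference (`a - b`) together with a summary of each input.
#'
#' @param a,b Tibbles from [minor_groove_widths()].
#' @return List with `by_level` (tibble: `level`, `width_a`, `width_b`,
#'   `delta`), `summary_a`, `summary_b`.
#' @export
compare_profiles <- function(a, b) {
  shared <- dplyr::inner_join(
    dplyr::select(as_tibble(a), "level", width_a = "width_A"),
    dplyr::select(as_tibble(b), "level", width_b = "width_A"),
    by = "level"
  )
  if (nrow(shared) == 0L) abort("Profiles share no levels; cannot compare.")
  list(
    by_level = dplyr::mutate(shared, delta = .data$width_a - .data$width_b),
    summary_a = groove_summary(a),
    summary_b = groove_summary(b)
  )
}

#' Plot a groove profile
#'
#' @param object A `groove_profile` tibble.
#' @param ... Unused.
#' @method autoplot groove_profile
#' @export
autoplot.groove_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$level, y = .data$width_A)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "base-pair level (5'->3', reference strand)",
                  y = "minor groove width (A)") +
    ggplot2::theme_minimal()
}
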