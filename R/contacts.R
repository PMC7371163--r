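#' Minimum-image distance in an orthorhombic box
#'
#' Euclidean distance between points `a` and `b`, minimised over all
#' periodic images of `b` in an orthorhombic cell. Because the cell is
#' rectangular the minimisation separates by axis.
#'
#' @param a,b Numeric length-3 vectors, or (n x 3) matrices for vectorised
#'   use (in Angstrom).
#' @param box Length-3 vector of box edge lengths (Angstrom).
#' @return Distance(s) in Angstrom.
#' @export
#' @examples
#' min_image_distance(c(0.5, 0, 0), c(9.5, 0, 0), c(10, 10, 10)) # 1
min_image_distance <- function(a, b, box) {
  a <- rbind(a)
  b <- rbind(b)
  box <- as.numeric(box)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  if (any(!is.finite(box)) || any(box <= 0)) {
    stop("box lengths must be finite and > 0", call. = FALSE)
  }
  d <- a - b
  d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  out <- sqrt(rowSums(d^2))
  if (length(out) == 1) out[[1]] else out
}

#' Detect protein-lipid heavy-atom contacts
#'
#' Finds, for every frame, all pairs of one protein heavy atom and one lipid
#' heavy atom whose minimum-image distance is strictly below the threshold
#' (default 3.5 Angstrom). Hydrogens never participate. The search uses a
#' cell-list spatial hash but is exactly equivalent to the all-pairs
#' computation.
#'
#' @param frames A `mem_frames`.
#' @param topology A `mem_topology` consistent with `frames`.
#' @param threshold Contact threshold in Angstrom; pairs at exactly the
#'   threshold are excluded (strict `<`).
#' @param use_pbc Apply the minimum-image convention (default `TRUE`). With
#'   `FALSE`, plain Euclidean distances are used.
#' @param species Lipid species to consider: any of `"PIP2_P4"`,
#'   `"PIP2_P5"`, `"POPA"`, `"OTHER_LIPID"`, or the shorthand `"PIP2"`
#'   (both protonation species) / `"all"` (default).
#' @return A `mem_contacts` tibble, one row per contact per frame, with
#'   columns `frame`, `time_ns`, `chain_id`, `residue_number`,
#'   `residue_name`, `protein_atom`, `protein_atom_name`, `lipid_atom`,
#'   `lipid_atom_name`, `lipid_molecule`, `species`, `distance_A`.
#'   Attributes `n_frames`, `time_ns`, `threshold` record the analysis
#'   window.
#' @export
find_contacts <- function(frames, topology, threshold = 3.5, use_pbc = TRUE,
                          species = "all") {
  check_frames_topology(frames, topology)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be a positive length in Angstrom", call. = FALSE)
  }
  species <- intersect(resolve_species(species), lipid_species())

  at <- topology$atoms
  ip <- which(at$species == "PROTEIN" & at$is_heavy)
  il <- which(at$species %in% species & at$is_heavy)

  nf <- n_frames(frames)
  res <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- frames$coords[, , f, drop = FALSE]
    dim(xyz) <- dim(xyz)[1:2]
    hits <- contact_pairs_cell(
      xyz[ip, , drop = FALSE], xyz[il, , drop = FALSE],
      frames$box[f, ], threshold, use_pbc
    )
    if (length(hits$i) == 0) next
    pa <- ip[hits$i]
    la <- il[hits$j]
    res[[f]] <- tibble::tibble(
      frame = f,
      time_ns = frames$time_ns[f],
      chain_id = at$chain_id[pa],
      residue_number = at$residue_number[pa],
      residue_name = at$residue_name[pa],
      protein_atom = at$atom_index[pa],
      protein_atom_name = at$atom_name[pa],
      lipid_atom = at$atom_index[la],
      lipid_atom_name = at$atom_name[la],
      lipid_molecule = at$molecule_id[la],
      species = at$species[la],
      distance_A = hits$distance
    )
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      frame = integer(), time_ns = numeric(), chain_id = character(),
      residue_number = integer(), residue_name = character(),
      protein_atom = integer(), protein_atom_name = character(),
      lipid_atom = integer(), lipid_atom_name = character(),
      lipid_molecule = integer(), species = character(),
      distance_A = numeric()
    )
  }
  out <- out |> dplyr::arrange(.data$frame, .data$protein_atom, .data$lipid_atom)
  new_contacts(out,
    n_frames = nf, time_ns = frames$time_ns,
    threshold = threshold
  )
}

new_contacts <- function(tbl, n_frames, time_ns, threshold) {
  structure(
    tbl,
    n_frames = n_frames, time_ns = time_ns, threshold = threshold,
    class = c("mem_contacts", class(tibble::as_tibble(tbl)))
  )
}

# Number of frames in the window a contact table was computed over. Falls
# back to the largest frame index when the attribute was stripped by
# data-frame surgery.
contacts_n_frames <- function(contacts, n_frames = NULL) {
  n <- n_frames %||% attr(contacts, "n_frames") %||%
    (if (nrow(contacts) > 0) max(contacts$frame) else 0L)
  if (n < 1) stop("empty analysis window", call. = FALSE)
  as.integer(n)
}

#' Per-frame contact counts for a residue selection
#'
#' Time series of the number of heavy-atom contact pairs between a set of
#' protein residues and a lipid species, one value per frame (frames with no
#' contacts count zero). Supports segment-level profiles such as an
#' N-terminal (residues 1-325) versus C-terminal (326-933) split.
#'
#' @param contacts A `mem_contacts` table from [find_contacts()].
#' @param residues Integer vector of residue numbers to include (all chains);
#'   `NULL` means every protein residue.
#' @param species Lipid species selector (see [find_contacts()]); default
#'   `"PIP2"`.
#' @param n_frames Number of frames in the window; taken from the contact
#'   table's attributes when omitted.
#' @return A tibble with columns `frame`, `time_ns`, `n_contacts`.
#' @export
contact_series <- function(contacts, residues = NULL, species = "PIP2",
                           n_frames = NULL) {
  nf <- contacts_n_frames(contacts, n_frames)
  sel <- resolve_species(species)
  x <- contacts |> dplyr::filter(.data$species %in% sel)
  if (!is.null(residues)) {
    if (length(residues) == 0) stop("residue selection is empty", call. = FALSE)
    x <- x |> dplyr::filter(.data$residue_number %in% residues)
  }
  counts <- x |> dplyr::count(.data$frame, name = "n_contacts")
  time_ns <- attr(contacts, "time_ns")
  tibble::tibble(frame = seq_len(nf)) |>
    dplyr::left_join(counts, by = "frame") |>
    dplyr::mutate(
      n_contacts = tidyr::replace_na(.data$n_contacts, 0L),
      time_ns = if (!is.null(time_ns)) time_ns[.data$frame] else NA_real_
    ) |>
    dplyr::select("frame", "time_ns", "n_contacts")
}
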