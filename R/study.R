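#' Generate the package's reference synthetic study
#'
#' Desk-scale stand-in for a protein/bilayer binding trajectory: the lower
#' leaflet of a composition manifest is scaled down to a toy leaflet
#' (default 60 lipids, preserving the PIP2/POPA fractions and the 1:1 PIP2
#' protonation split), and a seeded contact schedule with known ground
#' truth is planted on it. The schedule mixes permanently bound residues
#' (2-4 pairs per frame, one PIP2 partner each), a residue alternating
#' between two PIP2 partners every frame, intermittently bound residues
#' (one pair in roughly 60% of frames), and a permanent POPA binder, so
#' that means, SEs, lifetimes, partner counts and site ratios all take
#' non-trivial values recoverable from the ledger.
#'
#' @param pip2_percent Lower-leaflet PIP2 percentage (default 10).
#' @param n_frames Frames in the trajectory (default 50; with the default
#'   0.24 ns frame interval this is a 12 ns toy window that divides into 5
#'   equal blocks).
#' @param n_protein_residues Protein length (default 12).
#' @param toy_leaflet Toy lower-leaflet size (default 60 lipids).
#' @param seed Integer seed; fixes schedule and geometry.
#' @return As [make_toy_system()], plus `schedule` (the planted per-frame
#'   schedule) and `composition` (the full-scale manifest).
#' @export
make_study_system <- function(pip2_percent = 10, n_frames = 50,
                              n_protein_residues = 12, toy_leaflet = 60,
                              seed = 1) {
  comp <- make_composition(pip2_percent)
  lower <- comp$leaflets[comp$leaflets$leaflet == "lower", ]
  frac <- toy_leaflet / lower$total
  n_pip2 <- max(1, round(lower$PIP2 * frac))
  n_popa <- max(1, round(lower$POPA * frac))
  n_other <- max(1, toy_leaflet - n_pip2 - n_popa)
  lipid_counts <- c(
    PIP2_P4 = ceiling(n_pip2 / 2), PIP2_P5 = floor(n_pip2 / 2),
    POPA = n_popa, OTHER_LIPID = n_other
  )
  n_pip2 <- lipid_counts[["PIP2_P4"]] + lipid_counts[["PIP2_P5"]]
  pip2_ids <- seq_len(n_pip2)
  popa_ids <- n_pip2 + seq_len(lipid_counts[["POPA"]])

  set.seed(as.integer(seed))
  sched <- list()
  # permanently bound residues, one PIP2 partner each, fixed pair count
  n_strong <- min(4, n_pip2, n_protein_residues)
  for (r in seq_len(n_strong)) {
    k <- sample(2:4, 1)
    sched[[length(sched) + 1]] <- tibble::tibble(
      frame = seq_len(n_frames), residue = r, lipid = pip2_ids[r], n_pairs = k
    )
  }
  # one residue alternating between two PIP2 partners every frame
  if (n_pip2 >= n_strong + 2 && n_protein_residues >= n_strong + 1) {
    r <- n_strong + 1
    alt <- pip2_ids[n_strong + 1:2]
    sched[[length(sched) + 1]] <- tibble::tibble(
      frame = seq_len(n_frames), residue = r,
      lipid = alt[(seq_len(n_frames) - 1) %% 2 + 1], n_pairs = 1L
    )
  }
  # intermittently bound residues (~60% of frames, random PIP2 partner)
  inter <- setdiff(seq(n_strong + 2, length.out = 3), 0)
  inter <- inter[inter <= n_protein_residues]
  for (r in inter) {
    on <- sort(sample(n_frames, round(0.6 * n_frames)))
    sched[[length(sched) + 1]] <- tibble::tibble(
      frame = on, residue = r, lipid = sample(pip2_ids, 1), n_pairs = 1L
    )
  }
  # a permanent POPA binder
  r_popa <- n_strong + 5
  if (r_popa <= n_protein_residues && length(popa_ids) > 0) {
    sched[[length(sched) + 1]] <- tibble::tibble(
      frame = seq_len(n_frames), residue = r_popa, lipid = popa_ids[1],
      n_pairs = 2L
    )
  }
  schedule <- dplyr::bind_rows(sched) |>
    dplyr::arrange(.data$frame, .data$residue)

  lipids <- rep(names(lipid_counts), times = lipid_counts)
  sys <- make_schedule_trajectory(
    schedule,
    lipids = lipids, n_frames = n_frames,
    n_protein_residues = n_protein_residues, seed = seed
  )
  sys$schedule <- schedule
  sys$composition <- comp
  sys
}
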