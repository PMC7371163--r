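# Synthetic membrane systems with planted, ground-truth protein-lipid
# contacts. Lipids are coarse stand-ins (named headgroup atoms + a few tail
# beads) carrying CHARMM-style atom names so species rules and the PIP2 site
# map apply unchanged; no physical realism is claimed. Geometry is
# engineered so that planted pairs sit exactly at their stated distance and
# every other protein-lipid heavy-atom pair is at least threshold + margin
# away, making the ground truth unambiguous.

#' Bilayer composition manifest
#'
#' Builds per-leaflet lipid counts for an asymmetric bilayer whose inner
#' (lower) leaflet carries the anionic lipids. At 10% and 1% PIP2 the counts
#' are the reference compositions (600 lipids per leaflet: at 10%, lower
#' leaflet PIP2 60 / cholesterol 180 / POPC 90 / POPE 150 / POPA 60 /
#' PSM 60); other percentages interpolate the PIP2/POPA counts linearly and
#' rebalance POPC/POPE proportionally so leaflet totals are preserved. PIP2
#' is split 1:1 into the 4- and 5-protonated species (differing by at most
#' one when odd). Hydration is 144 waters per lipid.
#'
#' @param pip2_percent PIP2 percentage of the lower leaflet (0-100).
#' @param leaflet_size Lipids per leaflet (default 600).
#' @param waters_per_lipid Hydration factor (default 144).
#' @param salt_molarity Target salt concentration in mol/L (default 0.15).
#' @return A `mem_composition`: list with `leaflets` (tibble of counts per
#'   leaflet), `n_lipids`, `n_waters`, and the parameters.
#' @export
#' @examples
#' make_composition(10)$leaflets
make_composition <- function(pip2_percent, leaflet_size = 600,
                             waters_per_lipid = 144, salt_molarity = 0.15) {
  if (!is.numeric(pip2_percent) || pip2_percent < 0 || pip2_percent > 100) {
    stop("pip2_percent must be in [0, 100]", call. = FALSE)
  }
  if (!is.numeric(leaflet_size) || leaflet_size <= 0) {
    stop("leaflet_size must be positive", call. = FALSE)
  }
  s <- leaflet_size / 600
  p <- pip2_percent

  upper <- round(c(PIP2 = 0, CHL1 = 210, POPC = 240, POPE = 30, POPA = 0, PSM = 120) * s)

  pip2 <- round(leaflet_size * p / 100)
  popa <- pip2
  psm <- round(60 * s)
  chol <- max(0, round((210 - 10 * (p - 1) / 3) * s))
  remaining <- leaflet_size - pip2 - popa - psm - chol
  if (remaining < 0) {
    stop("composition infeasible: anionic lipids exceed the leaflet size",
      call. = FALSE
    )
  }
  popc_t <- max(0, 144 - 6 * (p - 1))
  pope_t <- max(0, 174 - 24 * (p - 1) / 9)
  popc <- if (popc_t + pope_t > 0) round(remaining * popc_t / (popc_t + pope_t)) else 0
  pope <- remaining - popc
  lower <- c(PIP2 = pip2, CHL1 = chol, POPC = popc, POPE = pope, POPA = popa, PSM = psm)

  leaflets <- dplyr::bind_rows(
    tibble::tibble(leaflet = "upper", !!!as.list(upper)),
    tibble::tibble(leaflet = "lower", !!!as.list(lower))
  ) |>
    dplyr::mutate(
      PIP2_P4 = ceiling(.data$PIP2 / 2),
      PIP2_P5 = floor(.data$PIP2 / 2),
      total = .data$PIP2 + .data$CHL1 + .data$POPC + .data$POPE +
        .data$POPA + .data$PSM
    )
  n_lipids <- sum(leaflets$total)
  structure(
    list(
      leaflets = leaflets,
      n_lipids = n_lipids,
      n_waters = waters_per_lipid * n_lipids,
      waters_per_lipid = waters_per_lipid,
      salt_molarity = salt_molarity,
      pip2_percent = pip2_percent,
      leaflet_size = leaflet_size
    ),
    class = "mem_composition"
  )
}

#' @export
print.mem_composition <- function(x, ...) {
  cat("<mem_composition> ", x$pip2_percent, "% PIP2, ",
    x$leaflet_size, " lipids/leaflet, ", x$n_waters, " waters\n",
    sep = ""
  )
  print(x$leaflets)
  invisible(x)
}

#' @export
#' @rdname tidy_memlens
tidy.mem_composition <- function(x, ...) x$leaflets

# --- Toy lipid / residue templates -----------------------------------------

toy_lipid_atoms <- function(species) {
  switch(species,
    PIP2_P4 = ,
    PIP2_P5 = c(
      "C11", "C12", "C13", "C14", "C15", "C16",
      "P", "O11", "O12", "O13", "O14",
      "P4", "O4", "OP42", "OP43", "OP44",
      "P5", "O5", "OP52", "OP53", "OP54"
    ),
    POPA = c("P", "O11", "O12", "O13", "O14", "C1", "C2"),
    OTHER_LIPID = c("P", "N", "C1", "C2"),
    stop("no toy template for species ", species, call. = FALSE)
  )
}

# 4-character aliases of the CHARMM SAPI24/SAPI25 residue names, so the
# toy systems stay within the standard PDB residue-name column width.
toy_lipid_resname <- function(species) {
  switch(species,
    PIP2_P4 = "PI24", PIP2_P5 = "PI25",
    POPA = "POPA", OTHER_LIPID = "POPC"
  )
}

# Preferred contact-atom order per species; PIP2 order cycles through the
# three phosphate groups before the ring, so multi-pair schedules exercise
# several site categories deterministically.
toy_contact_atoms <- function(species) {
  switch(species,
    PIP2_P4 = ,
    PIP2_P5 = c(
      "P4", "P5", "P", "OP42", "OP52", "O13",
      "OP43", "OP53", "O12", "C11", "C12", "C13"
    ),
    POPA = c("P", "O12", "O13", "O14", "C1", "C2"),
    OTHER_LIPID = c("P", "N", "C1", "C2")
  )
}

# Site category of a PIP2 atom given its species (matches build_site_map
# with the default phosphate atom names).
toy_site_category <- function(species, atom_name) {
  if (!species %in% c("PIP2_P4", "PIP2_P5")) {
    return(NA_character_)
  }
  pa <- default_phosphate_atoms()
  if (atom_name %in% pa$P1) {
    "P1np"
  } else if (atom_name %in% pa$P4) {
    if (species == "PIP2_P4") "P4p" else "P4np"
  } else if (atom_name %in% pa$P5) {
    if (species == "PIP2_P5") "P5p" else "P5np"
  } else {
    "OTHER"
  }
}

toy_protein_heavy <- c("N", "CA", "C", "O", "CB")

#' Generate a toy membrane system with planted contacts
#'
#' Builds a deterministic topology and trajectory containing a short protein
#' chain and coarse lipids, with an explicit ledger of planted protein-lipid
#' heavy-atom contacts. Each planted pair is realised at exactly its stated
#' distance; every non-planted protein-lipid heavy-atom pair is guaranteed
#' to be at least `threshold + margin` apart (verified at generation time),
#' so contact detection must recover the ledger exactly. Contacts flagged
#' `wrapped` are placed across a periodic boundary: their unwrapped distance
#' exceeds the threshold while the minimum-image distance equals the planted
#' value.
#'
#' @param n_protein_residues Number of protein residues (each 5 heavy atoms
#'   plus one hydrogen).
#' @param lipid_counts Named integer vector of lower-leaflet lipids, names
#'   in `PIP2_P4`, `PIP2_P5`, `POPA`, `OTHER_LIPID`.
#' @param n_frames Number of trajectory frames.
#' @param planted Data frame of planted contacts with columns `frame`,
#'   `residue` (residue number), `lipid` (lipid index, 1-based in
#'   `lipid_counts` order), and optionally `atom_name` (lipid contact atom;
#'   default cycles the species' contact atoms), `distance_A` (default 3.2)
#'   and `wrapped` (default `FALSE`). `NULL` plants nothing.
#' @param n_upper Bystander lipids in the (PIP2/POPA-free) upper leaflet.
#' @param box Length-3 box in Angstrom, or `NULL` to size automatically.
#' @param seed Integer seed controlling grid jitter; same seed, same system.
#' @param threshold,margin Exclusion guarantee: non-planted pairs are kept
#'   at least `threshold + margin` apart (defaults 3.5 and 0.5 Angstrom).
#' @param frame_interval_ns Time between frames in ns.
#' @param validate Verify the exclusion guarantee by an all-pairs
#'   minimum-image sweep over every frame (default `TRUE`).
#' @return A list: `topology` (`mem_topology`), `frames` (`mem_frames`),
#'   `ledger` (tibble: `frame`, `chain_id`, `residue_number`,
#'   `protein_atom`, `lipid_atom`, `lipid_molecule`, `species`,
#'   `site_category`, `distance_A`, `wrapped`).
#' @export
make_toy_system <- function(n_protein_residues = 8,
                            lipid_counts = c(
                              PIP2_P4 = 2, PIP2_P5 = 2,
                              POPA = 1, OTHER_LIPID = 1
                            ),
                            n_frames = 1, planted = NULL, n_upper = 0,
                            box = NULL, seed = 1, threshold = 3.5,
                            margin = 0.5, frame_interval_ns = 0.24,
                            validate = TRUE) {
  stopifnot(n_protein_residues >= 1, n_frames >= 1)
  bad <- setdiff(names(lipid_counts), c("PIP2_P4", "PIP2_P5", "POPA", "OTHER_LIPID"))
  if (length(bad) > 0) {
    stop("unsupported lipid species in lipid_counts: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  species_vec <- rep(names(lipid_counts), times = lipid_counts)
  n_lip <- length(species_vec)
  upper_vec <- rep("OTHER_LIPID", n_upper)

  res_spacing <- 15
  atom_pitch <- 2.5
  lipid_pitch <- 12

  ncol_grid <- max(1L, ceiling(sqrt(max(n_lip, n_upper, 1))))
  if (is.null(box)) {
    bx <- max(10 + n_protein_residues * res_spacing, 10 + ncol_grid * lipid_pitch) + 10
    nrow_grid <- ceiling(max(n_lip, n_upper, 1) / ncol_grid)
    bz <- max(40, 20 + nrow_grid * lipid_pitch)
    box <- c(bx, 60, bz)
  }
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths", call. = FALSE)
  if (10 + n_protein_residues * res_spacing > box[1]) {
    stop("infeasible geometry: protein does not fit in the box", call. = FALSE)
  }

  y_prot <- box[2] / 2
  y_lower <- y_prot + 20
  y_upper <- y_prot - 20
  if (box[2] < 2 * (threshold + margin) + 1) {
    stop("infeasible geometry: box too small for the exclusion margin", call. = FALSE)
  }

  # ---- topology -----------------------------------------------------------
  resnames <- rep(
    c("ALA", "ARG", "SER", "THR", "MET", "LYS", "GLY", "VAL"),
    length.out = n_protein_residues
  )
  prot_atoms <- tibble::tibble(
    atom_name = rep(c(toy_protein_heavy, "HA"), n_protein_residues),
    element = rep(c("N", "C", "C", "O", "C", "H"), n_protein_residues),
    residue_name = rep(resnames, each = 6),
    residue_number = rep(seq_len(n_protein_residues), each = 6),
    chain_id = "A"
  )
  all_lip <- c(species_vec, upper_vec)
  lip_atoms <- purrr::imap(all_lip, function(sp, l) {
    nm <- toy_lipid_atoms(sp)
    tibble::tibble(
      atom_name = nm,
      element = substr(nm, 1, 1),
      residue_name = toy_lipid_resname(sp),
      residue_number = l,
      chain_id = "L"
    )
  }) |> dplyr::bind_rows()
  topology <- build_topology(dplyr::bind_rows(prot_atoms, lip_atoms))
  at <- topology$atoms

  # ---- base coordinates ---------------------------------------------------
  set.seed(as.integer(seed))
  coords0 <- matrix(0, nrow = nrow(at), ncol = 3)
  # protein: residue r occupies x = 10 + (r-1)*15 + {0, 2.5, 5, 7.5, 10};
  # the hydrogen rides 1 A above the CA.
  for (r in seq_len(n_protein_residues)) {
    ii <- which(at$chain_id == "A" & at$residue_number == r)
    base <- 10 + (r - 1) * res_spacing
    heavy_x <- base + (0:4) * atom_pitch
    coords0[ii[1:5], ] <- cbind(heavy_x, y_prot, box[3] / 2)
    coords0[ii[6], ] <- c(heavy_x[2], y_prot, box[3] / 2 + 1.0)
  }
  # lipids: jittered grid, one cell per molecule, atoms in a compact cluster
  jitter_xz <- function(n) round(stats::runif(n, -0.3, 0.3), 2)
  place_leaflet <- function(indices_by_mol, y_home) {
    n <- length(indices_by_mol)
    if (n == 0) {
      return()
    }
    jx <- jitter_xz(n)
    jz <- jitter_xz(n)
    for (l in seq_len(n)) {
      ii <- indices_by_mol[[l]]
      gx <- 6 + ((l - 1) %% ncol_grid) * lipid_pitch + jx[l]
      gz <- 6 + ((l - 1) %/% ncol_grid) * lipid_pitch + jz[l]
      k <- seq_along(ii) - 1
      coords0[ii, ] <<- cbind(
        gx + (k %% 5) * 1.0, y_home, gz + (k %/% 5) * 1.0
      )
    }
  }
  lower_mols <- lapply(seq_len(n_lip), function(l) {
    which(at$chain_id == "L" & at$residue_number == l)
  })
  upper_mols <- lapply(seq_len(n_upper), function(l) {
    which(at$chain_id == "L" & at$residue_number == n_lip + l)
  })
  place_leaflet(lower_mols, y_lower)
  place_leaflet(upper_mols, y_upper)

  # ---- planted contacts ---------------------------------------------------
  ledger <- tibble::tibble(
    frame = integer(), chain_id = character(), residue_number = integer(),
    protein_atom = integer(), lipid_atom = integer(),
    lipid_molecule = integer(), species = character(),
    site_category = character(), distance_A = numeric(), wrapped = logical()
  )
  coords <- array(rep(coords0, n_frames), dim = c(nrow(at), 3, n_frames))

  if (!is.null(planted) && nrow(planted) > 0) {
    planted <- tibble::as_tibble(planted)
    if (!all(c("frame", "residue", "lipid") %in% names(planted))) {
      stop("planted needs columns frame, residue, lipid", call. = FALSE)
    }
    if (!"distance_A" %in% names(planted)) planted$distance_A <- 3.2
    if (!"wrapped" %in% names(planted)) planted$wrapped <- FALSE
    if (!"atom_name" %in% names(planted)) planted$atom_name <- NA_character_
    if (any(planted$frame < 1 | planted$frame > n_frames)) {
      stop("planted frame outside trajectory", call. = FALSE)
    }
    if (any(planted$lipid < 1 | planted$lipid > n_lip)) {
      stop("planted lipid index outside the lower leaflet", call. = FALSE)
    }
    if (any(planted$residue < 1 | planted$residue > n_protein_residues)) {
      stop("planted residue outside the protein", call. = FALSE)
    }
    if (any(planted$distance_A >= threshold)) {
      stop("planted distance must be below the contact threshold", call. = FALSE)
    }
    if (any(planted$distance_A <= 0) || any(planted$distance_A > box[2] / 2)) {
      stop("infeasible planted distance", call. = FALSE)
    }

    # protein atom slot: cycles within (frame, residue); lipid atom slot:
    # cycles within (frame, lipid) through the species' contact atoms.
    planted <- planted |>
      dplyr::group_by(.data$frame, .data$residue) |>
      dplyr::mutate(pslot = dplyr::row_number()) |>
      dplyr::group_by(.data$frame, .data$lipid) |>
      dplyr::mutate(lslot = dplyr::row_number()) |>
      dplyr::ungroup()
    if (any(planted$pslot > 5)) {
      stop("infeasible planting: more than 5 pairs on one residue in one frame",
        call. = FALSE
      )
    }

    led <- vector("list", nrow(planted))
    for (i in seq_len(nrow(planted))) {
      p <- planted[i, ]
      sp <- species_vec[p$lipid]
      lat_names <- toy_contact_atoms(sp)
      aname <- if (!is.na(p$atom_name)) {
        p$atom_name
      } else {
        if (p$lslot > length(lat_names)) {
          stop("infeasible planting: lipid ", p$lipid,
            " has no free contact atom in frame ", p$frame,
            call. = FALSE
          )
        }
        lat_names[p$lslot]
      }
      mol_ii <- lower_mols[[p$lipid]]
      la <- mol_ii[match(aname, at$atom_name[mol_ii])]
      if (is.na(la)) {
        stop("atom ", aname, " not present in ", sp, " toy lipid", call. = FALSE)
      }
      pa <- which(
        at$chain_id == "A" & at$residue_number == p$residue &
          at$atom_name == toy_protein_heavy[p$pslot]
      )
      target <- coords0[pa, ]
      dy <- if (p$wrapped) p$distance_A - box[2] else p$distance_A
      coords[la, , p$frame] <- c(target[1], target[2] + dy, target[3])
      led[[i]] <- tibble::tibble(
        frame = as.integer(p$frame),
        chain_id = "A",
        residue_number = as.integer(p$residue),
        protein_atom = at$atom_index[pa],
        lipid_atom = at$atom_index[la],
        lipid_molecule = at$molecule_id[la],
        species = sp,
        site_category = toy_site_category(sp, aname),
        distance_A = p$distance_A,
        wrapped = isTRUE(p$wrapped)
      )
    }
    ledger <- dplyr::bind_rows(led)
    if (anyDuplicated(ledger[, c("frame", "protein_atom", "lipid_atom")]) > 0) {
      stop("infeasible planting: duplicate (frame, protein atom, lipid atom)",
        call. = FALSE
      )
    }
  }

  frames <- new_frames(coords, box, frame_interval_ns = frame_interval_ns)
  if (validate) {
    validate_planted(topology, frames, ledger, threshold, margin)
  }
  list(topology = topology, frames = frames, ledger = ledger)
}

# All-pairs minimum-image sweep asserting the planted/excluded geometry.
validate_planted <- function(topology, frames, ledger, threshold, margin) {
  at <- topology$atoms
  ip <- which(at$species == "PROTEIN" & at$is_heavy)
  il <- which(at$species %in% lipid_species() & at$is_heavy)
  for (f in seq_len(n_frames(frames))) {
    xyz <- frames$coords[, , f]
    box <- frames$box[f, ]
    d2 <- matrix(0, length(ip), length(il))
    for (d in 1:3) {
      dx <- outer(xyz[ip, d], xyz[il, d], "-")
      dx <- dx - box[d] * round(dx / box[d])
      d2 <- d2 + dx^2
    }
    dd <- sqrt(d2)
    lf <- ledger[ledger$frame == f, ]
    pi <- match(lf$protein_atom, at$atom_index[ip])
    li <- match(lf$lipid_atom, at$atom_index[il])
    planted_mask <- matrix(FALSE, length(ip), length(il))
    planted_mask[cbind(pi, li)] <- TRUE
    if (nrow(lf) > 0 && any(abs(dd[cbind(pi, li)] - lf$distance_A) > 1e-8)) {
      stop("internal generation error: planted distance not realised", call. = FALSE)
    }
    if (any(dd[!planted_mask] < threshold + margin)) {
      stop("infeasible planting: a non-planted pair violates the exclusion margin",
        call. = FALSE
      )
    }
  }
  invisible(TRUE)
}

#' Generate a trajectory realising a per-residue contact schedule
#'
#' Converts a tidy contact schedule — how many heavy-atom contact pairs each
#' residue makes with which lipid molecule in each frame — into a toy
#' trajectory whose analysis reproduces the schedule exactly: per-residue
#' window means, lifetimes, distinct partner counts and distinct-lipid
#' summaries all equal the schedule-derived values.
#'
#' @param schedule Data frame with columns `frame`, `residue`, `lipid`, and
#'   `n_pairs` (default 1 if absent).
#' @param lipids Character vector giving the species of each lipid index;
#'   defaults to alternating `PIP2_P4`/`PIP2_P5` up to the largest scheduled
#'   lipid index.
#' @param n_frames Total frames; defaults to the largest scheduled frame.
#' @param distance_A Planted contact distance (default 3.2).
#' @inheritParams make_toy_system
#' @return As [make_toy_system()].
#' @export
make_schedule_trajectory <- function(schedule, lipids = NULL, n_frames = NULL,
                                     n_protein_residues = NULL,
                                     distance_A = 3.2, seed = 1, ...) {
  schedule <- tibble::as_tibble(schedule)
  if (nrow(schedule) > 0 && !all(c("frame", "residue", "lipid") %in% names(schedule))) {
    stop("schedule needs columns frame, residue, lipid", call. = FALSE)
  }
  if (!"n_pairs" %in% names(schedule)) schedule$n_pairs <- 1L
  if (nrow(schedule) > 0 && any(schedule$n_pairs < 1)) {
    stop("n_pairs must be >= 1", call. = FALSE)
  }
  max_lip <- if (nrow(schedule) > 0) max(schedule$lipid) else 1L
  if (is.null(lipids)) {
    lipids <- rep(c("PIP2_P4", "PIP2_P5"), length.out = max_lip)
  }
  if (max_lip > length(lipids)) {
    stop("schedule references lipid indices beyond the lipid list", call. = FALSE)
  }
  if (is.null(n_frames)) {
    n_frames <- if (nrow(schedule) > 0) max(schedule$frame) else 1L
  }
  if (is.null(n_protein_residues)) {
    n_protein_residues <- if (nrow(schedule) > 0) max(schedule$residue) else 4L
  }
  planted <- if (nrow(schedule) > 0) {
    schedule |>
      dplyr::rowwise() |>
      dplyr::reframe(
        frame = .data$frame, residue = .data$residue, lipid = .data$lipid,
        pair = seq_len(.data$n_pairs)
      ) |>
      dplyr::mutate(distance_A = distance_A, wrapped = FALSE) |>
      dplyr::select(-"pair")
  } else {
    NULL
  }
  counts <- table(factor(lipids, levels = c("PIP2_P4", "PIP2_P5", "POPA", "OTHER_LIPID")))
  # keep lipid indices aligned with the species order used by make_toy_system
  ord <- order(match(lipids, c("PIP2_P4", "PIP2_P5", "POPA", "OTHER_LIPID")))
  remap <- match(seq_along(lipids), ord)
  if (!is.null(planted)) planted$lipid <- remap[planted$lipid]
  make_toy_system(
    n_protein_residues = n_protein_residues,
    lipid_counts = stats::setNames(as.integer(counts), names(counts)),
    n_frames = n_frames, planted = planted, seed = seed, ...
  )
}
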