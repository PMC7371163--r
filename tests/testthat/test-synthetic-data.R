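test_that("the 10% composition manifest reproduces the reference counts", {
  comp <- make_composition(10)
  lf <- comp$leaflets
  up <- lf[lf$leaflet == "upper", ]
  lo <- lf[lf$leaflet == "lower", ]

  expect_equal(
    unlist(lo[, c("PIP2", "CHL1", "POPC", "POPE", "POPA", "PSM")]),
    c(PIP2 = 60, CHL1 = 180, POPC = 90, POPE = 150, POPA = 60, PSM = 60)
  )
  expect_equal(
    unlist(up[, c("PIP2", "CHL1", "POPC", "POPE", "POPA", "PSM")]),
    c(PIP2 = 0, CHL1 = 210, POPC = 240, POPE = 30, POPA = 0, PSM = 120)
  )
  expect_equal(lo$total, 600)
  expect_equal(up$total, 600)
  expect_equal(lo$PIP2_P4, 30)
  expect_equal(lo$PIP2_P5, 30)
  expect_equal(comp$n_lipids, 1200)
  expect_equal(comp$n_waters, 144 * 1200)
})

test_that("the 1% composition manifest reproduces the reference counts", {
  lf <- make_composition(1)$leaflets
  lo <- lf[lf$leaflet == "lower", ]
  up <- lf[lf$leaflet == "upper", ]
  expect_equal(
    unlist(lo[, c("PIP2", "CHL1", "POPC", "POPE", "POPA", "PSM")]),
    c(PIP2 = 6, CHL1 = 210, POPC = 144, POPE = 174, POPA = 6, PSM = 60)
  )
  # upper leaflet is PIP2/POPA-free and identical across conditions
  expect_equal(
    unlist(up[, c("PIP2", "CHL1", "POPC", "POPE", "POPA", "PSM")]),
    c(PIP2 = 0, CHL1 = 210, POPC = 240, POPE = 30, POPA = 0, PSM = 120)
  )
  expect_equal(lo$total, 600)
})

test_that("intermediate compositions preserve totals and the 1:1 PIP2 split", {
  for (p in c(0, 2.5, 5, 7, 20)) {
    lf <- make_composition(p)$leaflets
    expect_equal(lf$total, c(600, 600))
    lo <- lf[lf$leaflet == "lower", ]
    expect_equal(lo$PIP2_P4 + lo$PIP2_P5, lo$PIP2)
    expect_lte(abs(lo$PIP2_P4 - lo$PIP2_P5), 1)
    expect_equal(lo$POPA, lo$PIP2) # POPA tracks PIP2 in the inner leaflet
    expect_true(all(unlist(lo[, c("CHL1", "POPC", "POPE", "PSM")]) >= 0))
  }
  expect_error(make_composition(-1), "0, 100")
  expect_error(make_composition(101), "0, 100")
  expect_error(make_composition(10, leaflet_size = 0), "positive")
  # beyond ~1/3 anionic lipids the leaflet cannot hold the companion species
  expect_error(make_composition(60), "infeasible")
})

test_that("toy systems realise planted distances exactly", {
  pl <- data.frame(
    frame = c(1, 1, 2), residue = c(1, 3, 2), lipid = c(1, 4, 5),
    distance_A = c(3.2, 3.3, 3.45)
  )
  sys <- make_toy_system(n_frames = 2, planted = pl, seed = 31)
  ct <- find_contacts(sys$frames, sys$topology)
  led <- sys$ledger |> dplyr::arrange(frame, protein_atom, lipid_atom)
  got <- ct |> dplyr::arrange(frame, protein_atom, lipid_atom)
  expect_equal(got$protein_atom, led$protein_atom)
  expect_equal(got$lipid_atom, led$lipid_atom)
  expect_equal(got$distance_A, led$distance_A, tolerance = 1e-9)
  expect_equal(got$species, led$species)
})

test_that("every non-planted pair respects the exclusion margin", {
  pl <- data.frame(frame = 1, residue = c(1, 2), lipid = c(1, 2))
  sys <- make_toy_system(n_frames = 1, planted = pl, seed = 32)
  at <- sys$topology$atoms
  ip <- which(at$species == "PROTEIN" & at$is_heavy)
  il <- which(at$species != "PROTEIN" & at$species != "SOLVENT" & at$is_heavy)
  xyz <- sys$frames$coords[, , 1]
  box <- sys$frames$box[1, ]
  planted_keys <- paste(sys$ledger$protein_atom, sys$ledger$lipid_atom)
  for (i in ip) {
    for (j in il) {
      d <- oracle_min_image(xyz[i, ], xyz[j, ], box)
      if (paste(at$atom_index[i], at$atom_index[j]) %in% planted_keys) {
        expect_lt(d, 3.5)
      } else {
        expect_gte(d, 4.0) # threshold 3.5 + margin 0.5
      }
    }
  }
})

test_that("generation is deterministic in the seed and varies across seeds", {
  a <- make_toy_system(n_frames = 2, seed = 7)
  b <- make_toy_system(n_frames = 2, seed = 7)
  c <- make_toy_system(n_frames = 2, seed = 8)
  expect_identical(a$frames$coords, b$frames$coords)
  expect_false(identical(a$frames$coords, c$frames$coords))
})

test_that("infeasible planting requests fail loudly", {
  expect_error(
    make_toy_system(planted = data.frame(frame = 2, residue = 1, lipid = 1)),
    "outside trajectory"
  )
  expect_error(
    make_toy_system(planted = data.frame(frame = 1, residue = 99, lipid = 1)),
    "outside the protein"
  )
  expect_error(
    make_toy_system(planted = data.frame(frame = 1, residue = 1, lipid = 99)),
    "outside the lower leaflet"
  )
  expect_error(
    make_toy_system(planted = data.frame(
      frame = 1, residue = 1, lipid = 1, distance_A = 3.6
    )),
    "below the contact threshold"
  )
  expect_error(
    make_toy_system(planted = data.frame(
      frame = 1, residue = 1, lipid = 1:6
    )),
    "more than 5 pairs"
  )
})

test_that("a wrapped planted contact is only seen through the minimum image", {
  pl <- data.frame(frame = 1, residue = 2, lipid = 1, wrapped = TRUE)
  sys <- make_toy_system(n_frames = 1, planted = pl, seed = 33)
  led <- sys$ledger
  xyz <- sys$frames$coords[, , 1]
  at <- sys$topology$atoms
  i <- which(at$atom_index == led$protein_atom)
  j <- which(at$atom_index == led$lipid_atom)
  raw <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  expect_gt(raw, 3.5) # unwrapped separation is not a contact
  expect_equal(
    min_image_distance(xyz[i, ], xyz[j, ], sys$frames$box[1, ]),
    led$distance_A
  )
  expect_equal(nrow(find_contacts(sys$frames, sys$topology)), 1)
  expect_equal(nrow(find_contacts(sys$frames, sys$topology, use_pbc = FALSE)), 0)
})

test_that("schedule trajectories expand n_pairs and keep species labels", {
  sched <- tibble::tibble(
    frame = c(1, 1, 2, 2),
    residue = c(1, 2, 1, 2),
    lipid = c(1, 2, 1, 3),
    n_pairs = c(3, 1, 2, 1)
  )
  sys <- make_schedule_trajectory(
    sched,
    lipids = c("PIP2_P4", "POPA", "PIP2_P5")
  )
  expect_equal(nrow(sys$ledger), 7)
  ct <- find_contacts(sys$frames, sys$topology)
  expect_equal(nrow(ct), 7)
  s1 <- contact_series(ct, residues = 1, species = "all")
  expect_equal(s1$n_contacts, c(3L, 2L))
  # lipid 2 was declared POPA and must come back as POPA
  popa <- ct |> dplyr::filter(species == "POPA")
  expect_equal(nrow(popa), 1)
  expect_equal(popa$residue_number, 2L)
  expect_equal(popa$frame, 1L)
})

test_that("the reference study system matches its schedule and composition", {
  sys <- make_study_system(n_frames = 10, seed = 5)
  expect_s3_class(sys$composition, "mem_composition")
  expect_equal(sys$composition$pip2_percent, 10)

  ct <- find_contacts(sys$frames, sys$topology)
  per_res <- sys$schedule |>
    dplyr::group_by(residue) |>
    dplyr::summarise(n = sum(n_pairs), .groups = "drop")
  got <- ct |>
    dplyr::group_by(residue_number) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
  expect_equal(got$residue_number, per_res$residue)
  expect_equal(got$n, per_res$n)
})
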