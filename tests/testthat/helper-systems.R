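# Tiny fixtures built in code.

# One protein atom (ALA CA) and one POPA phosphorus at a chosen separation
# along x, for threshold-semantics checks.
two_atom_system <- function(distance, box = c(20, 20, 20)) {
  topo <- build_topology(tibble::tibble(
    atom_name = c("CA", "P"),
    element = c("C", "P"),
    residue_name = c("ALA", "POPA"),
    residue_number = c(1L, 1L),
    chain_id = c("A", "L")
  ))
  coords <- matrix(c(
    5, 5, 5,
    5 + distance, 5, 5
  ), ncol = 3, byrow = TRUE)
  list(topology = topo, frames = new_frames(coords, box))
}

# Random unlabelled coordinates dressed as a protein/lipid system so
# find_contacts can run on them: na protein carbons + nb POPA oxygens.
random_two_set_system <- function(na, nb, box, seed) {
  set.seed(seed)
  atoms <- tibble::tibble(
    atom_name = c(rep("CA", na), rep("O12", nb)),
    element = c(rep("C", na), rep("O", nb)),
    residue_name = c(rep("ALA", na), rep("POPA", nb)),
    residue_number = c(seq_len(na), seq_len(nb)),
    chain_id = c(rep("A", na), rep("L", nb))
  )
  topo <- build_topology(atoms)
  coords <- cbind(
    stats::runif(na + nb, 0, box[1]),
    stats::runif(na + nb, 0, box[2]),
    stats::runif(na + nb, 0, box[3])
  )
  list(
    topology = topo, frames = new_frames(coords, box),
    A = coords[seq_len(na), , drop = FALSE],
    B = coords[na + seq_len(nb), , drop = FALSE]
  )
}

minimal_pdb_lines <- function() {
  c(
    "CRYST1   30.000   30.000   30.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  N   ALA A   1       5.000   5.000   5.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       6.400   5.000   5.000  1.00  0.00           C",
    "ATOM      3  HA  ALA A   1       6.400   6.000   5.000  1.00  0.00           H",
    "ATOM      4  P   POPAL   1       8.500   5.000   5.000  1.00  0.00           P",
    "ATOM      5  O12 POPAL   1       9.900   5.000   5.000  1.00  0.00           O",
    "ATOM      6  OH2 TIP3W   1      20.000  20.000  20.000  1.00  0.00           O",
    "END"
  )
}
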