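#' Default residue-name to species rules
#'
#' Maps residue names to the molecule-species vocabulary used throughout the
#' package: `PROTEIN`, `PIP2_P4` (PIP2 singly protonated at the 4-phosphate),
#' `PIP2_P5` (protonated at the 5-phosphate), `POPA`, `OTHER_LIPID`,
#' `SOLVENT`, and `ION`. The defaults follow CHARMM residue naming
#' (`SAPI24`/`SAPI25` for the two PIP2 protonation species) plus the twenty
#' standard amino acids.
#'
#' @return A named character vector: names are residue names, values are
#'   species labels.
#' @export
#' @examples
#' default_species_rules()[c("SAPI24", "POPC", "ARG")]
default_species_rules <- function() {
  aa <- c(
    "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HSD",
    "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR",
    "TRP", "TYR", "VAL"
  )
  c(
    stats::setNames(rep("PROTEIN", length(aa)), aa),
    SAPI24 = "PIP2_P4", SAPI25 = "PIP2_P5",
    PI24 = "PIP2_P4", PI25 = "PIP2_P5",
    POPA = "POPA",
    POPC = "OTHER_LIPID", POPE = "OTHER_LIPID", PSM = "OTHER_LIPID",
    CHL1 = "OTHER_LIPID",
    TIP3 = "SOLVENT", HOH = "SOLVENT", WAT = "SOLVENT",
    POT = "ION", K = "ION", CLA = "ION", CL = "ION", SOD = "ION", NA. = "ION"
  )
}

#' Species labels recognised by the analysis
#' @keywords internal
species_vocabulary <- function() {
  c("PROTEIN", "PIP2_P4", "PIP2_P5", "POPA", "OTHER_LIPID", "SOLVENT", "ION")
}

lipid_species <- function() c("PIP2_P4", "PIP2_P5", "POPA", "OTHER_LIPID")

# Expand user-facing species selectors: "PIP2" covers both protonation
# species; "all" covers every lipid species.
resolve_species <- function(species) {
  if (is.null(species)) {
    return(lipid_species())
  }
  out <- unlist(lapply(species, function(s) {
    switch(s,
      PIP2 = c("PIP2_P4", "PIP2_P5"),
      all = lipid_species(),
      s
    )
  }), use.names = FALSE)
  bad <- setdiff(out, species_vocabulary())
  if (length(bad) > 0) {
    stop("unknown species label(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  unique(out)
}

# Hydrogen detection: element column first; when blank, an atom name whose
# first letter after stripping leading digits is H is hydrogen (common
# force-field naming such as "1HB", "HG21").
infer_is_heavy <- function(element, atom_name) {
  element <- toupper(trimws(element))
  name_core <- sub("^[0-9]+", "", toupper(trimws(atom_name)))
  from_name <- !substr(name_core, 1, 1) %in% "H"
  ifelse(element == "", from_name, element != "H")
}

#' Read a topology from a PDB file
#'
#' Parses ATOM/HETATM records, classifies every atom as heavy or hydrogen,
#' groups atoms into molecules, and assigns each molecule a species from its
#' residue name. Lipids, solvent and ions are grouped into molecules by
#' (residue name, residue number, chain/segment); the protein is grouped by
#' chain, one molecule per chain.
#'
#' @param path Path to a PDB file.
#' @param species_rules Named character vector mapping residue names to
#'   species (see [default_species_rules()]).
#' @return A `mem_topology` object: a list with `atoms` (one row per atom:
#'   `atom_index` 0-based, `atom_name`, `element`, `residue_name`,
#'   `residue_number`, `chain_id`, `is_heavy`, `molecule_id`, `species`) and
#'   `molecules` tibbles.
#' @export
read_topology <- function(path, species_rules = default_species_rules()) {
  if (!file.exists(path)) {
    stop("topology file not found: ", path, call. = FALSE)
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) {
      stop("failed to parse PDB file '", path, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  at <- pdb$atom
  atoms <- tibble::tibble(
    atom_index = seq_len(nrow(at)) - 1L,
    atom_name = trimws(at$elety),
    element = ifelse(is.na(at$elesy), "", trimws(at$elesy)),
    residue_name = trimws(at$resid),
    residue_number = as.integer(at$resno),
    chain_id = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  )
  build_topology(atoms, species_rules = species_rules)
}

#' Build a topology from an atom table
#'
#' Lower-level constructor used by [read_topology()] and the synthetic-data
#' generators. Assigns `is_heavy`, species, and molecule ids.
#'
#' @param atoms Data frame with columns `atom_name`, `residue_name`,
#'   `residue_number`, `chain_id`, and optionally `element` and
#'   `atom_index`.
#' @inheritParams read_topology
#' @return A `mem_topology` object.
#' @export
build_topology <- function(atoms, species_rules = default_species_rules()) {
  atoms <- tibble::as_tibble(atoms)
  if (!"element" %in% names(atoms)) atoms$element <- ""
  atoms$atom_index <- seq_len(nrow(atoms)) - 1L
  atoms$residue_number <- as.integer(atoms$residue_number)

  unknown <- setdiff(unique(atoms$residue_name), names(species_rules))
  if (length(unknown) > 0) {
    stop(
      "residue name(s) not covered by species rules: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  atoms$species <- unname(species_rules[atoms$residue_name])
  atoms$is_heavy <- infer_is_heavy(atoms$element, atoms$atom_name)

  # Protein molecules are whole chains; everything else is one molecule per
  # (residue name, residue number, chain).
  mol_key <- ifelse(
    atoms$species == "PROTEIN",
    paste0("prot|", atoms$chain_id),
    paste0(atoms$residue_name, "|", atoms$residue_number, "|", atoms$chain_id)
  )
  atoms$molecule_id <- match(mol_key, unique(mol_key))

  molecules <- atoms |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::summarise(
      species = .data$species[1],
      residue_name = .data$residue_name[1],
      chain_id = .data$chain_id[1],
      n_atoms = dplyr::n(),
      n_heavy = sum(.data$is_heavy),
      .groups = "drop"
    )

  prot <- atoms[atoms$species == "PROTEIN", ]
  if (nrow(prot) > 0) {
    dup <- prot |>
      dplyr::distinct(.data$chain_id, .data$residue_number, .data$residue_name) |>
      dplyr::count(.data$chain_id, .data$residue_number) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      stop("duplicate protein (chain, residue_number) pairs in topology",
        call. = FALSE
      )
    }
  }

  structure(
    list(atoms = atoms, molecules = molecules),
    class = "mem_topology"
  )
}

#' @export
print.mem_topology <- function(x, ...) {
  cat("<mem_topology> ", nrow(x$atoms), " atoms, ",
    nrow(x$molecules), " molecules\n",
    sep = ""
  )
  tab <- table(x$molecules$species)
  for (s in names(tab)) cat("  ", s, ": ", tab[[s]], "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname tidy_memlens
tidy.mem_topology <- function(x, ...) x$atoms

n_atoms <- function(topology) nrow(topology$atoms)

# Protein residues as a tibble keyed by (chain_id, residue_number).
protein_residues <- function(topology) {
  topology$atoms |>
    dplyr::filter(.data$species == "PROTEIN") |>
    dplyr::distinct(.data$chain_id, .data$residue_number, .data$residue_name)
}
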