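#' Default PIP2 phosphate-group atom names
#'
#' Heavy atoms of the three inositol phosphate groups of PIP2, named per
#' CHARMM conventions: the phosphorus plus its terminal oxygens, and (by
#' default) the ester oxygen linking the group to the ring carbon. The
#' 1-phosphate bridges the inositol ring to the glycerol backbone.
#'
#' @param include_ester Include the ring-side ester oxygen of the 4- and
#'   5-phosphates (`O4`, `O5`) in the group (default `TRUE`).
#' @return Named list with character vectors `P1`, `P4`, `P5`.
#' @export
default_phosphate_atoms <- function(include_ester = TRUE) {
  list(
    P1 = c("P", "O11", "O12", "O13", "O14"),
    P4 = c("P4", if (include_ester) "O4", "OP42", "OP43", "OP44"),
    P5 = c("P5", if (include_ester) "O5", "OP52", "OP53", "OP54")
  )
}

site_categories <- function() c("P1np", "P4p", "P5p", "P4np", "P5np", "OTHER")

#' Build a PIP2 binding-site map
#'
#' Assigns every heavy atom of the two PIP2 protonation species to one of
#' six binding-site categories: `P1np` (the 1-phosphate, never protonated),
#' `P4p`/`P4np` and `P5p`/`P5np` (the 4- and 5-phosphate, protonated or
#' not depending on species), and `OTHER` (all remaining heavy atoms,
#' including the inositol ring, glycerol and acyl chains). For the species
#' protonated at the 4-phosphate, the P4 group maps to `P4p` and the P5
#' group to `P5np`; the 5-protonated species is the mirror image.
#'
#' @param topology A `mem_topology` containing at least one PIP2 molecule.
#' @param phosphate_atoms Atom names of each phosphate group (see
#'   [default_phosphate_atoms()]).
#' @return A tibble with columns `species`, `atom_name`, `category` — the
#'   site map, a partition of each species' heavy atoms.
#' @export
build_site_map <- function(topology, phosphate_atoms = default_phosphate_atoms()) {
  stopifnot(all(c("P1", "P4", "P5") %in% names(phosphate_atoms)))
  at <- topology$atoms
  maps <- lapply(c("PIP2_P4", "PIP2_P5"), function(sp) {
    mol <- at[at$species == sp & at$is_heavy, ]
    if (nrow(mol) == 0) {
      return(NULL)
    }
    names_sp <- unique(mol$atom_name)
    missing <- setdiff(unlist(phosphate_atoms), names_sp)
    if (length(missing) > 0) {
      stop(
        "phosphate atom name(s) not present in ", sp, " molecules: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    category <- rep("OTHER", length(names_sp))
    category[names_sp %in% phosphate_atoms$P1] <- "P1np"
    category[names_sp %in% phosphate_atoms$P4] <-
      if (sp == "PIP2_P4") "P4p" else "P4np"
    category[names_sp %in% phosphate_atoms$P5] <-
      if (sp == "PIP2_P5") "P5p" else "P5np"
    tibble::tibble(species = sp, atom_name = names_sp, category = category)
  })
  maps <- dplyr::bind_rows(maps)
  if (nrow(maps) == 0) {
    stop("topology contains no PIP2 molecules; site categories are undefined",
      call. = FALSE
    )
  }
  maps
}

# Join site categories onto PIP2 contact rows.
classify_contacts <- function(contacts, site_map) {
  pip <- contacts |>
    dplyr::filter(.data$species %in% c("PIP2_P4", "PIP2_P5")) |>
    dplyr::left_join(
      dplyr::rename(site_map, lipid_atom_name = "atom_name"),
      by = c("species", "lipid_atom_name")
    )
  if (anyNA(pip$category)) {
    stop("site map does not cover every contacted PIP2 atom", call. = FALSE)
  }
  pip
}

#' Binding-site ratios of PIP2 contacts
#'
#' Distributes a set of PIP2 contact instances (each atom pair in each frame
#' counted once) over the six binding-site categories and reports
#' percentages. Typically applied to one residue's contacts over an
#' analysis window.
#'
#' @param contacts PIP2 contact rows (a `mem_contacts` table or subset).
#' @param site_map Site map from [build_site_map()].
#' @return A one-row tibble with columns `P1np`, `P4p`, `P5p`, `P4np`,
#'   `P5np`, `OTHER`, each a percentage; they sum to 100. With zero PIP2
#'   contact instances the ratio is undefined and an error is raised.
#' @export
site_ratios <- function(contacts, site_map) {
  pip <- classify_contacts(contacts, site_map)
  if (nrow(pip) == 0) {
    stop("no PIP2 contact instances in the window; site ratio is undefined",
      call. = FALSE
    )
  }
  counts <- table(factor(pip$category, levels = site_categories()))
  pct <- 100 * as.numeric(counts) / sum(counts)
  tibble::as_tibble(as.list(stats::setNames(pct, site_categories())))
}
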