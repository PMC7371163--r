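#' Window-mean contacts per residue-lipid molecule pair
#'
#' Mean number of heavy-atom contact pairs per frame for every
#' (protein residue, individual lipid molecule) combination observed in the
#' window — the edge-weight table behind [build_network()].
#'
#' @inheritParams contact_series
#' @return A tibble: `chain_id`, `residue_number`, `residue_name`,
#'   `lipid_molecule`, `species`, `mean_contacts`.
#' @export
pair_means <- function(contacts, species = "all", n_frames = NULL) {
  nf <- contacts_n_frames(contacts, n_frames)
  sel <- resolve_species(species)
  contacts |>
    dplyr::filter(.data$species %in% sel) |>
    dplyr::group_by(
      .data$chain_id, .data$residue_number, .data$residue_name,
      .data$lipid_molecule, .data$species
    ) |>
    dplyr::summarise(mean_contacts = dplyr::n() / nf, .groups = "drop")
}

residue_node_id <- function(chain_id, residue_number) {
  paste0("res:", chain_id, ":", residue_number)
}
lipid_node_id <- function(lipid_molecule) paste0("lip:", lipid_molecule)

#' Build the protein-lipid interaction network
#'
#' Undirected bipartite graph whose nodes are protein residues and
#' individual lipid molecules, with an edge wherever the window-mean
#' heavy-atom contact count of the pair reaches the inclusion threshold.
#' Edge weight is that mean. Residue-residue and lipid-lipid edges do not
#' exist by construction.
#'
#' @inheritParams contact_series
#' @param min_weight Inclusion threshold on the window-mean contact count
#'   (default 1).
#' @param strict Use a strict `>` comparison instead of the default `>=`.
#' @param n_term_end Domain-label split passed through to residue nodes.
#' @return A `mem_network`: list with `graph` (igraph), `edges` (tibble),
#'   `nodes` (tibble with `node`, `kind`, `label`, `species`, `domain`,
#'   `degree`, `component`, `component_size`).
#' @export
build_network <- function(contacts, species = "all", min_weight = 1,
                          strict = FALSE, n_term_end = 325, n_frames = NULL) {
  if (!is.numeric(min_weight) || min_weight < 0) {
    stop("min_weight must be non-negative", call. = FALSE)
  }
  pm <- pair_means(contacts, species = species, n_frames = n_frames)
  keep <- if (strict) pm$mean_contacts > min_weight else pm$mean_contacts >= min_weight
  edges <- pm[keep, , drop = FALSE] |>
    dplyr::mutate(
      from = residue_node_id(.data$chain_id, .data$residue_number),
      to = lipid_node_id(.data$lipid_molecule),
      weight = .data$mean_contacts
    )

  if (nrow(edges) == 0) {
    nodes <- tibble::tibble(
      node = character(), kind = character(), label = character(),
      species = character(), domain = character()
    )
    g <- igraph::make_empty_graph(0, directed = FALSE)
    net <- structure(
      list(
        graph = g,
        edges = tibble::tibble(
          chain_id = character(), residue_number = integer(),
          residue_name = character(), lipid_molecule = integer(),
          species = character(), weight = numeric()
        ),
        nodes = nodes, min_weight = min_weight, strict = strict
      ),
      class = "mem_network"
    )
    net$nodes <- annotate_nodes(net)
    return(net)
  }

  res_nodes <- edges |>
    dplyr::distinct(
      node = .data$from, .data$chain_id, .data$residue_number,
      .data$residue_name
    ) |>
    dplyr::mutate(
      kind = "residue",
      label = paste0(.data$residue_name, .data$residue_number),
      species = NA_character_,
      domain = ifelse(.data$residue_number <= n_term_end, "N", "C")
    ) |>
    dplyr::select("node", "kind", "label", "species", "domain")
  lip_nodes <- edges |>
    dplyr::distinct(node = .data$to, .data$lipid_molecule, .data$species) |>
    dplyr::mutate(
      kind = "lipid",
      label = paste0(.data$species, "_", .data$lipid_molecule),
      domain = NA_character_
    ) |>
    dplyr::select("node", "kind", "label", "species", "domain")
  nodes <- dplyr::bind_rows(res_nodes, lip_nodes) |>
    dplyr::arrange(.data$node)

  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "weight")],
    directed = FALSE,
    vertices = nodes
  )

  net <- structure(
    list(
      graph = g,
      edges = tibble::as_tibble(edges[, c(
        "chain_id", "residue_number", "residue_name", "lipid_molecule",
        "species", "weight"
      )]),
      nodes = nodes,
      min_weight = min_weight,
      strict = strict
    ),
    class = "mem_network"
  )
  net$nodes <- annotate_nodes(net)
  net
}

# Degree and deterministic component labels (size desc, then smallest node
# id lexicographically).
annotate_nodes <- function(net) {
  g <- net$graph
  nodes <- net$nodes
  if (nrow(nodes) == 0) {
    return(dplyr::mutate(nodes,
      degree = integer(), component = integer(),
      component_size = integer()
    ))
  }
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  memb <- comp$membership
  key <- vapply(
    seq_len(comp$no),
    function(k) min(names(memb)[memb == k]),
    character(1)
  )
  ord <- order(-comp$csize, key)
  relabel <- match(seq_len(comp$no), ord)
  nodes$degree <- as.integer(deg[nodes$node])
  nodes$component <- relabel[memb[nodes$node]]
  nodes$component_size <- comp$csize[memb[nodes$node]]
  nodes
}

#' @export
print.mem_network <- function(x, ...) {
  cat("<mem_network> ", nrow(x$nodes), " nodes (",
    sum(x$nodes$kind == "residue"), " residues, ",
    sum(x$nodes$kind == "lipid"), " lipids), ",
    nrow(x$edges), " edges, ",
    if (nrow(x$nodes)) max(x$nodes$component) else 0, " clusters\n",
    sep = ""
  )
  invisible(x)
}

#' Connected components (clusters) of an interaction network
#'
#' @param network A `mem_network`.
#' @return A tibble of components ordered by size descending (ties by
#'   smallest node id): `component`, `n_nodes`, `n_residues`, `n_lipids`,
#'   `nodes` (list column of node ids).
#' @export
network_components <- function(network) {
  nodes <- network$nodes
  if (nrow(nodes) == 0) {
    return(tibble::tibble(
      component = integer(), n_nodes = integer(), n_residues = integer(),
      n_lipids = integer(), nodes = list()
    ))
  }
  nodes |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      n_nodes = dplyr::n(),
      n_residues = sum(.data$kind == "residue"),
      n_lipids = sum(.data$kind == "lipid"),
      nodes = list(sort(.data$node)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$component)
}

#' Export an interaction network
#'
#' Writes GraphML (node attributes `kind`, `label`, `species`, `domain`,
#' `degree`, `component`; edge attribute `weight`), SIF (interaction type
#' `contact`), or a tidy edge-list CSV. GraphML and SIF load directly into
#' Cytoscape.
#'
#' @param network A `mem_network`.
#' @param path Output file.
#' @param format One of `"graphml"`, `"sif"`, `"edgelist"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(network, path,
                           format = c("graphml", "sif", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- network$graph
    n <- network$nodes
    idx <- match(igraph::V(g)$name, n$node)
    igraph::V(g)$kind <- n$kind[idx]
    igraph::V(g)$label <- n$label[idx]
    igraph::V(g)$species <- ifelse(is.na(n$species[idx]), "", n$species[idx])
    igraph::V(g)$domain <- ifelse(is.na(n$domain[idx]), "", n$domain[idx])
    igraph::V(g)$degree <- n$degree[idx]
    igraph::V(g)$component <- n$component[idx]
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    e <- network$edges
    writeLines(
      sprintf(
        "%s\tcontact\t%s",
        residue_node_id(e$chain_id, e$residue_number),
        lipid_node_id(e$lipid_molecule)
      ),
      path
    )
  } else {
    utils::write.csv(network$edges, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GraphML network written by [export_network()]
#'
#' @param path GraphML file.
#' @return An igraph graph with the exported attributes.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' @export
#' @rdname tidy_memlens
tidy.mem_network <- function(x, ...) x$edges

#' @export
#' @rdname tidy_memlens
glance.mem_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_residues = sum(x$nodes$kind == "residue"),
    n_lipids = sum(x$nodes$kind == "lipid"),
    n_edges = nrow(x$edges),
    n_components = if (nrow(x$nodes)) max(x$nodes$component) else 0L,
    largest_component = if (nrow(x$nodes)) max(x$nodes$component_size) else 0L
  )
}
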