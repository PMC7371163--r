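#' Block-averaged mean and standard error
#'
#' Splits a per-frame series into `n_blocks` contiguous equal-sized blocks
#' and estimates the standard error of the mean as the sample standard
#' deviation of the block means divided by `sqrt(n_blocks)`. Block averaging
#' discounts the serial correlation of trajectory frames that makes the
#' naive SE of correlated samples too small. The default of 5 blocks suits a
#' 1000 ns window analysed as 5 x 200 ns.
#'
#' @param x Numeric per-frame series.
#' @param n_blocks Number of blocks (>= 2).
#' @param allow_ragged When the series length is not a multiple of
#'   `n_blocks`, drop the remainder frames at the tail (default is an
#'   error, keeping the SE semantics clean).
#' @return A one-row tibble: `mean` (grand mean), `se` (block SE), `sd`
#'   (frame-level standard deviation), `n_blocks`, `block_size`.
#' @export
#' @examples
#' block_stats(1:10, n_blocks = 5) # mean 5.5, se sqrt(2)
block_stats <- function(x, n_blocks = 5, allow_ragged = FALSE) {
  x <- as.numeric(x)
  if (!is.numeric(n_blocks) || n_blocks < 2) {
    stop("n_blocks must be at least 2 (the block SE is undefined otherwise)",
      call. = FALSE
    )
  }
  n_blocks <- as.integer(n_blocks)
  if (length(x) < n_blocks) {
    stop("series shorter than the number of blocks", call. = FALSE)
  }
  if (length(x) %% n_blocks != 0) {
    if (!allow_ragged) {
      stop(
        "series length ", length(x), " does not divide into ", n_blocks,
        " equal blocks; set allow_ragged = TRUE to truncate the tail",
        call. = FALSE
      )
    }
    x <- x[seq_len((length(x) %/% n_blocks) * n_blocks)]
  }
  bs <- length(x) %/% n_blocks
  bm <- vapply(
    seq_len(n_blocks),
    function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
    numeric(1)
  )
  tibble::tibble(
    mean = mean(x),
    se = stats::sd(bm) / sqrt(n_blocks),
    sd = stats::sd(x),
    n_blocks = n_blocks,
    block_size = bs
  )
}

#' Binding lifetime and lipid partner count of a residue
#'
#' The binding lifetime is the percentage of window frames in which the
#' residue has at least one heavy-atom contact with any molecule of the
#' species; the partner count is the number of distinct lipid molecules of
#' that species contacted at least once anywhere in the window.
#'
#' @inheritParams contact_series
#' @param residue Residue number (integer).
#' @param chain Optional chain id to disambiguate; `NULL` matches any chain.
#' @param topology Optional `mem_topology`; when supplied, a residue absent
#'   from the protein raises a lookup error instead of returning zeros.
#' @return A one-row tibble: `lifetime_percent`, `n_partners`.
#' @export
lifetime_and_partners <- function(contacts, residue, species = "PIP2",
                                  chain = NULL, topology = NULL,
                                  n_frames = NULL) {
  nf <- contacts_n_frames(contacts, n_frames)
  if (!is.null(topology)) {
    pr <- protein_residues(topology)
    known <- residue %in% pr$residue_number &
      (is.null(chain) || any(pr$chain_id[pr$residue_number == residue] == chain))
    if (!known) {
      stop("residue ", residue, " not found in the protein", call. = FALSE)
    }
  }
  sel <- resolve_species(species)
  x <- contacts |>
    dplyr::filter(
      .data$species %in% sel,
      .data$residue_number == residue,
      is.null(chain) | .data$chain_id %in% chain
    )
  tibble::tibble(
    lifetime_percent = 100 * dplyr::n_distinct(x$frame) / nf,
    n_partners = dplyr::n_distinct(x$lipid_molecule)
  )
}

#' Restrict a contact table to a time window
#'
#' Keeps contacts with `start_ns <= time_ns < end_ns` and renumbers the
#' retained frames consecutively so downstream per-frame statistics use the
#' window's frame count.
#'
#' @inheritParams contact_series
#' @param start_ns,end_ns Window bounds in ns (half-open).
#' @return A `mem_contacts` table over the window.
#' @export
clip_window <- function(contacts, start_ns, end_ns) {
  time_ns <- attr(contacts, "time_ns")
  if (is.null(time_ns)) {
    stop("contact table carries no frame time information", call. = FALSE)
  }
  keep <- which(time_ns >= start_ns & time_ns < end_ns)
  if (length(keep) == 0) stop("empty analysis window", call. = FALSE)
  out <- contacts |>
    dplyr::filter(.data$frame %in% keep) |>
    dplyr::mutate(frame = match(.data$frame, keep))
  new_contacts(out,
    n_frames = length(keep), time_ns = time_ns[keep],
    threshold = attr(contacts, "threshold")
  )
}

#' Ranked per-residue contact statistics
#'
#' The package's central summary: one row per protein residue whose
#' window-mean heavy-atom contact count with the chosen lipid species
#' reaches `min_mean`, ranked by mean contacts (ties broken by residue
#' number). Each row carries the block-averaged mean and SE, the
#' frame-level SD, the binding lifetime, the number of distinct lipid
#' partners, a domain label, and — for PIP2 with a site map — the six
#' binding-site ratio percentages.
#'
#' @inheritParams contact_series
#' @param min_mean Minimum window-mean contact count for a row to be kept
#'   (default 1).
#' @param n_blocks Blocks for the SE estimate (see [block_stats()]).
#' @param site_map Optional site map from [build_site_map()]; adds the six
#'   site-ratio columns to PIP2 rows.
#' @param n_term_end Last residue number of the N-terminal segment used for
#'   the domain label (default 325, the PX+PH region of human PLD2).
#' @param partner_mode `"cumulative"` (distinct partners anywhere in the
#'   window, the default) or `"simultaneous"` (maximum distinct partners in
#'   any single frame).
#' @param allow_ragged Passed to [block_stats()].
#' @return A tibble with columns `rank`, `chain_id`, `residue_number`,
#'   `residue_name`, `domain`, `mean_contacts`, `se_contacts`,
#'   `sd_contacts`, `lifetime_percent`, `n_partners`, and the site-ratio
#'   columns when applicable.
#' @export
residue_table <- function(contacts, species = "PIP2", min_mean = 1,
                          n_blocks = 5, site_map = NULL, n_term_end = 325,
                          partner_mode = c("cumulative", "simultaneous"),
                          allow_ragged = FALSE, n_frames = NULL) {
  partner_mode <- match.arg(partner_mode)
  nf <- contacts_n_frames(contacts, n_frames)
  sel <- resolve_species(species)
  x <- contacts |> dplyr::filter(.data$species %in% sel)

  empty <- tibble::tibble(
    rank = integer(), chain_id = character(), residue_number = integer(),
    residue_name = character(), domain = character(),
    mean_contacts = numeric(), se_contacts = numeric(),
    sd_contacts = numeric(), lifetime_percent = numeric(),
    n_partners = integer()
  )
  if (nrow(x) == 0) {
    return(empty)
  }

  want_ratio <- !is.null(site_map) &&
    any(sel %in% c("PIP2_P4", "PIP2_P5"))

  rows <- x |>
    dplyr::group_by(.data$chain_id, .data$residue_number, .data$residue_name) |>
    dplyr::group_map(function(g, key) {
      series <- integer(nf)
      per_frame <- table(g$frame)
      series[as.integer(names(per_frame))] <- as.integer(per_frame)
      bs <- block_stats(series, n_blocks = n_blocks, allow_ragged = allow_ragged)
      n_part <- if (partner_mode == "cumulative") {
        dplyr::n_distinct(g$lipid_molecule)
      } else {
        max(tapply(g$lipid_molecule, g$frame, dplyr::n_distinct))
      }
      row <- tibble::tibble(
        chain_id = key$chain_id,
        residue_number = key$residue_number,
        residue_name = key$residue_name,
        domain = ifelse(key$residue_number <= n_term_end, "N", "C"),
        mean_contacts = bs$mean,
        se_contacts = bs$se,
        sd_contacts = bs$sd,
        lifetime_percent = 100 * dplyr::n_distinct(g$frame) / nf,
        n_partners = as.integer(n_part)
      )
      if (want_ratio) {
        pip <- g[g$species %in% c("PIP2_P4", "PIP2_P5"), ]
        if (nrow(pip) > 0) {
          row <- dplyr::bind_cols(row, site_ratios(pip, site_map))
        }
      }
      row
    }) |>
    dplyr::bind_rows()

  rows <- rows |>
    dplyr::filter(.data$mean_contacts >= min_mean) |>
    dplyr::arrange(dplyr::desc(.data$mean_contacts), .data$residue_number) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  if (nrow(rows) == 0) empty else rows
}

#' Distinct interacting lipid molecules in a window
#'
#' Counts how many individual lipid molecules of a species touch the
#' protein. Two summaries are reported because "on average N lipids
#' interacted" can mean either: `distinct_over_window`, the number of
#' molecules with at least one protein contact anywhere in the window, and
#' `mean_per_frame`, the per-frame count of interacting molecules averaged
#' over frames.
#'
#' @inheritParams contact_series
#' @return A one-row tibble: `distinct_over_window`, `mean_per_frame`.
#' @export
distinct_lipid_summary <- function(contacts, species = "PIP2",
                                   n_frames = NULL) {
  nf <- contacts_n_frames(contacts, n_frames)
  sel <- resolve_species(species)
  x <- contacts |> dplyr::filter(.data$species %in% sel)
  per_frame <- x |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$lipid_molecule), .groups = "drop")
  tibble::tibble(
    distinct_over_window = dplyr::n_distinct(x$lipid_molecule),
    mean_per_frame = sum(per_frame$n) / nf
  )
}
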