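#' Construct a frame set
#'
#' Container for trajectory coordinates in an orthorhombic periodic box.
#'
#' @param coords Numeric array of dimension (n_atoms, 3, n_frames), in
#'   Angstrom. A single (n_atoms, 3) matrix is promoted to one frame.
#' @param box Numeric matrix (n_frames, 3) of box edge lengths in Angstrom,
#'   or a length-3 vector recycled over frames.
#' @param time_ns Frame time stamps in ns; defaults to
#'   `(0:(n_frames-1)) * frame_interval_ns`.
#' @param frame_interval_ns Time between saved frames in ns (default 0.24,
#'   i.e. 240 ps).
#' @return A `mem_frames` object.
#' @export
new_frames <- function(coords, box, time_ns = NULL, frame_interval_ns = 0.24) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  n_frames <- dim(coords)[3]
  if (is.null(dim(box))) {
    box <- matrix(rep(as.numeric(box), each = n_frames), nrow = n_frames)
  }
  box <- as.matrix(box)
  if (nrow(box) != n_frames || ncol(box) != 3) {
    stop("box must be an (n_frames x 3) matrix of edge lengths", call. = FALSE)
  }
  if (any(!is.finite(box)) || any(box <= 0)) {
    stop("box lengths must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (is.null(time_ns)) time_ns <- (seq_len(n_frames) - 1) * frame_interval_ns
  if (length(time_ns) != n_frames || any(time_ns < 0)) {
    stop("time_ns must be non-negative, one value per frame", call. = FALSE)
  }
  structure(
    list(coords = coords, box = box, time_ns = as.numeric(time_ns)),
    class = "mem_frames"
  )
}

#' @export
print.mem_frames <- function(x, ...) {
  cat("<mem_frames> ", dim(x$coords)[3], " frames x ", dim(x$coords)[1],
    " atoms; box [", paste(signif(x$box[1, ], 5), collapse = " x "),
    "] A; t = ", x$time_ns[1], "..", x$time_ns[length(x$time_ns)], " ns\n",
    sep = ""
  )
  invisible(x)
}

n_frames <- function(frames) dim(frames$coords)[3]

frame_coords <- function(frames, i) {
  x <- frames$coords[, , i, drop = FALSE]
  dim(x) <- dim(x)[1:2]
  x
}

check_frames_topology <- function(frames, topology) {
  if (dim(frames$coords)[1] != n_atoms(topology)) {
    stop(
      "atom-count mismatch: trajectory has ", dim(frames$coords)[1],
      " atoms, topology has ", n_atoms(topology),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Read trajectory frames
#'
#' Reads a coordinate trajectory from a CHARMM/NAMD-dialect DCD file (with
#' unit-cell records) or a multi-model PDB (box from CRYST1). Only
#' orthorhombic boxes are supported; triclinic cells raise an error. Frame
#' time stamps are assigned as frame index times `frame_interval_ns`, not
#' taken from the file header.
#'
#' @param path DCD or multi-model PDB file.
#' @param topology A `mem_topology`; the atom counts must agree.
#' @inheritParams new_frames
#' @return A `mem_frames` object, frames in file order.
#' @export
read_frames <- function(path, topology, frame_interval_ns = 0.24) {
  if (!file.exists(path)) {
    stop("trajectory file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    cell <- bio3d::read.dcd(path, cell = TRUE, verbose = FALSE)
    if (ncol(xyz) %% 3 != 0) stop("malformed DCD coordinate block", call. = FALSE)
    nat <- ncol(xyz) / 3
    nf <- nrow(xyz)
    ang <- cell[, 4:6, drop = FALSE]
    if (any(abs(ang - 90) > 1e-3)) {
      stop("triclinic unit cell encountered; only orthorhombic boxes are supported",
        call. = FALSE
      )
    }
    box <- cell[, 1:3, drop = FALSE]
    coords <- array(NA_real_, dim = c(nat, 3, nf))
    for (i in seq_len(nf)) {
      coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    cr <- grep("^CRYST1", lines, value = TRUE)
    if (length(cr) == 0) {
      stop("no CRYST1 record: box required for periodic analysis", call. = FALSE)
    }
    box1 <- as.numeric(c(
      substr(cr[1], 7, 15), substr(cr[1], 16, 24), substr(cr[1], 25, 33)
    ))
    angs <- as.numeric(c(
      substr(cr[1], 34, 40), substr(cr[1], 41, 47), substr(cr[1], 48, 54)
    ))
    if (any(abs(angs - 90) > 1e-3)) {
      stop("triclinic unit cell encountered; only orthorhombic boxes are supported",
        call. = FALSE
      )
    }
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
    nat <- ncol(xyz) / 3
    nf <- nrow(xyz)
    coords <- array(NA_real_, dim = c(nat, 3, nf))
    for (i in seq_len(nf)) {
      coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    }
    box <- matrix(rep(box1, each = nf), nrow = nf)
  }
  frames <- new_frames(coords, box, frame_interval_ns = frame_interval_ns)
  check_frames_topology(frames, topology)
  frames
}

# --- PDB writing ------------------------------------------------------------

cryst1_line <- function(box) {
  sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    box[1], box[2], box[3], 90, 90, 90
  )
}

# Fixed-width PDB v3 ATOM records: residue names up to 4 characters occupy
# columns 18-21 with the chain id at 22 (the CHARMM lipid convention), which
# bio3d reads back correctly.
pdb_atom_lines <- function(topology, xyz) {
  at <- topology$atoms
  name4 <- ifelse(
    nchar(at$atom_name) < 4,
    sprintf(" %-3s", at$atom_name),
    at$atom_name
  )
  sprintf(
    "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    at$atom_index + 1L, name4, at$residue_name, at$chain_id,
    at$residue_number, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
    sprintf("%2s", at$element)
  )
}

# --- DCD writing ------------------------------------------------------------
# CHARMM-dialect DCD: Fortran unformatted records (int32 byte-count framing),
# 'CORD' header with the crystal flag set, one 6-double unit-cell record per
# frame (a, cos(gamma), b, cos(beta), cos(alpha), c) followed by X/Y/Z
# single-precision coordinate records. Little-endian, as written by CHARMM,
# NAMD and OpenMM on commodity hardware.
write_dcd <- function(frames, path) {
  nf <- n_frames(frames)
  nat <- dim(frames$coords)[1]
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)

  rec <- function(writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    writer()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }

  icntrl <- integer(20)
  icntrl[1] <- nf # number of frames
  icntrl[2] <- 1L # first step
  icntrl[3] <- 1L # save interval (steps)
  icntrl[4] <- nf # total steps
  icntrl[11] <- 1L # crystal (unit-cell records present)
  icntrl[20] <- 24L # CHARMM version
  rec(function() {
    writeBin(charToRaw("CORD"), con)
    writeBin(icntrl, con, size = 4, endian = "little")
  }, 84)

  title <- formatC("Created by memlens", width = 80, flag = "-")
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeBin(charToRaw(title), con)
  }, 84)

  rec(function() writeBin(as.integer(nat), con, size = 4, endian = "little"), 4)

  for (i in seq_len(nf)) {
    b <- frames$box[i, ]
    cellrec <- c(b[1], 0, b[2], 0, 0, b[3])
    rec(function() {
      writeBin(as.numeric(cellrec), con, size = 8, endian = "little")
    }, 48)
    xyz <- frames$coords[, , i]
    for (ax in 1:3) {
      rec(function() {
        writeBin(as.numeric(xyz[, ax]), con, size = 4, endian = "little")
      }, 4 * nat)
    }
  }
  invisible(path)
}

#' Write a topology/trajectory pair
#'
#' Writes the topology as a PDB file (with a CRYST1 record from the first
#' frame's box) and the trajectory either as a CHARMM-dialect DCD with
#' unit-cell records or as a multi-model PDB, chosen by the trajectory file
#' extension. Output is deterministic given identical inputs.
#'
#' @param topology A `mem_topology`.
#' @param frames A `mem_frames` with at least one frame.
#' @param topology_path Output PDB path.
#' @param trajectory_path Output trajectory path (`.dcd` or `.pdb`).
#' @return Invisibly, a list of the two paths.
#' @export
write_system <- function(topology, frames, topology_path, trajectory_path) {
  if (!inherits(frames, "mem_frames") || n_frames(frames) < 1) {
    stop("at least one frame is required", call. = FALSE)
  }
  check_frames_topology(frames, topology)

  writeLines(
    c(
      cryst1_line(frames$box[1, ]),
      pdb_atom_lines(topology, frame_coords(frames, 1)),
      "END"
    ),
    topology_path
  )

  if (grepl("\\.dcd$", trajectory_path, ignore.case = TRUE)) {
    write_dcd(frames, trajectory_path)
  } else {
    lines <- cryst1_line(frames$box[1, ])
    for (i in seq_len(n_frames(frames))) {
      lines <- c(
        lines, sprintf("MODEL     %4d", i),
        pdb_atom_lines(topology, frame_coords(frames, i)), "ENDMDL"
      )
    }
    writeLines(c(lines, "END"), trajectory_path)
  }
  invisible(list(topology = topology_path, trajectory = trajectory_path))
}
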