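#' Write an XYZ trajectory frame
#'
#' Standard XYZ layout: atom count, a comment line carrying the time
#' stamp, then `name x y z` per atom.  Frames are appended to build a
#' trajectory.
#'
#' @param path file path.
#' @param positions n-by-3 coordinates (\enc{Å}{A}).
#' @param names atom names (recycled).
#' @param time time stamp (ps) written on the comment line.
#' @param append append to an existing file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(path, positions, names = "C", time = 0,
                      append = FALSE) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  names <- rep_len(names, n)
  lines <- c(
    as.character(n),
    sprintf("t= %.6f ps", time),
    sprintf("%-4s %14.8f %14.8f %14.8f", names,
            positions[, 1L], positions[, 2L], positions[, 3L]))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path file path.
#' @return list of frames; each frame has `positions` (n-by-3), `names`
#'   and `time` (ps, NA if the comment line carries none).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n < 1L) {
      stop(sprintf("%s:%d: expected an atom count, got '%s'",
                   path, ln, lines[ln]))
    }
    if (ln + 1L + n > length(lines)) {
      stop(sprintf("%s:%d: truncated frame (%d atoms declared)",
                   path, ln, n))
    }
    cm <- lines[ln + 1L]
    tm <- regmatches(cm, regexec("t= *([-0-9.eE+]+)", cm))[[1L]]
    time <- if (length(tm) == 2L) as.numeric(tm[2L]) else NA_real_
    body <- lines[(ln + 2L):(ln + 1L + n)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(lengths(toks) < 4L)
    if (length(bad)) {
      stop(sprintf("%s:%d: malformed atom line", path, ln + 1L + bad[1L]))
    }
    pos <- t(vapply(toks, function(x) as.numeric(x[2:4]), numeric(3L)))
    if (any(!is.finite(pos))) {
      stop(sprintf("%s: non-numeric coordinates in frame at line %d",
                   path, ln))
    }
    frames[[length(frames) + 1L]] <- list(
      positions = pos,
      names = vapply(toks, `[`, "", 1L),
      time = time)
    ln <- ln + 2L + n
  }
  frames
}

#' Write a structure as PDB
#'
#' Uses bio3d to emit a standard PDB with chain identifiers, so frames
#' are readable by any structure viewer.  Coordinates round-trip at the
#' format's 1e-3 \enc{Å}{A} precision.
#'
#' @param path file path.
#' @param topology an [topology()] object.
#' @param positions n-by-3 coordinates.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(path, topology, positions) {
  stopifnot(inherits(topology, "sg_topology"))
  positions <- as.matrix(positions)
  n <- topology$n_atoms
  chain_lab <- chain_letters(topology$chain)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(positions)),
    type = rep("ATOM", n),
    eleno = seq_len(n),
    elety = rep_len(topology$name, n),
    resid = rep("GLY", n),
    chain = chain_lab,
    resno = seq_len(n),
    o = rep(1, n), b = rep(0, n))
  invisible(path)
}

chain_letters <- function(chain) {
  ids <- unique(chain)
  labs <- c(LETTERS, letters, as.character(0:9))
  labs[((match(chain, ids) - 1L) %% length(labs)) + 1L]
}

#' Read a structure file
#'
#' Reads coordinates, atom names and chain identifiers from a PDB file
#' (via bio3d) or an XYZ file (first frame), and reconstructs a
#' bead-chain topology: consecutive atoms sharing a chain identifier are
#' bonded with the supplied rest length and force constant, and angle
#' terms are added along each chain.
#'
#' @param path file path ending in `.pdb` or `.xyz`.
#' @param mass bead mass (g/mol) for the rebuilt topology.
#' @param bond_fc,angle_fc force constants for the rebuilt bonded terms.
#' @param eps,sigma Lennard-Jones parameters.
#' @return list with `topology` and `positions`.
#' @export
read_structure <- function(path, mass = 100, bond_fc = 100, angle_fc = 10,
                           eps = 0.6, sigma = 1.6) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path)
    pos <- matrix(pdb$xyz, ncol = 3L, byrow = TRUE)
    chain <- pdb$atom$chain
    chain[is.na(chain)] <- "A"
    name <- pdb$atom$elety
  } else if (ext == "xyz") {
    fr <- read_xyz(path)[[1L]]
    pos <- fr$positions
    chain <- rep("A", nrow(pos))
    name <- fr$names
  } else {
    stop("unsupported structure format: ", path)
  }
  n <- nrow(pos)
  bonds <- NULL
  angles <- NULL
  if (n >= 2L) {
    same <- chain[-1L] == chain[-n]
    i <- which(same)
    if (length(i)) {
      d <- sqrt(rowSums((pos[i + 1L, , drop = FALSE] -
                           pos[i, , drop = FALSE])^2))
      bonds <- data.frame(i = i, j = i + 1L, r0 = round(mean(d), 6L),
                          fc = bond_fc)
    }
    both <- which(same[-length(same)] & same[-1L])
    if (length(both) && angle_fc > 0) {
      angles <- data.frame(i = both, j = both + 1L, k = both + 2L,
                           theta0 = pi, fc = angle_fc)
    }
  }
  top <- topology(mass = rep(mass, n), bonds = bonds, angles = angles,
                  eps = eps, sigma = sigma, chain = chain, name = name)
  list(topology = top, positions = pos)
}
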