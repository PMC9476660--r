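#' Write / read trajectories (XYZ and DCD)
#'
#' `write_trajectory` dispatches on the file extension: `.xyz` writes the
#' plain-text XYZ format (full double precision), `.dcd` the CHARMM/NAMD
#' binary DCD format (single precision).  `read_trajectory` reads either
#' back into a bare `cg_trajectory` (coordinates and times only).
#'
#' @param traj a `cg_trajectory`
#' @param path output file; extension selects the format
#' @param labels bead labels for the XYZ name column
#' @return `write_trajectory`: the path, invisibly; `read_trajectory`: a
#'   `cg_trajectory`
#' @export
write_trajectory <- function(traj, path, labels = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         xyz = write_xyz(traj, path, labels),
         dcd = write_dcd(traj, path),
         stop("unsupported trajectory format: ", ext))
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         xyz = read_xyz(path),
         dcd = read_dcd(path),
         stop("unsupported trajectory format: ", ext))
}

write_xyz <- function(traj, path, labels = NULL) {
  n <- traj$n_beads
  if (is.null(labels)) labels <- rep("CG", n)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(n), con)
    writeLines(sprintf("t= %.6f ps", traj$times[f]), con)
    xyz <- traj$coords[f, , , drop = TRUE]
    if (n == 1) xyz <- matrix(xyz, 1, 3)
    writeLines(sprintf("%-4s %17.9f %17.9f %17.9f", labels,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(); pos <- 1
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) break
    if (pos + 1 + n > length(lines))
      stop("truncated XYZ file: incomplete final frame")
    tm <- regmatches(lines[pos + 1],
                     regexec("t= *([-0-9.eE+]+)", lines[pos + 1]))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else
      length(times) + 1)
    block <- lines[(pos + 2):(pos + 1 + n)]
    sp <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1]] <-
      matrix(as.numeric(sp[, 2:4]), n, 3)
    pos <- pos + 2 + n
  }
  .traj_from_frames(frames, times)
}

.traj_from_frames <- function(frames, times) {
  nf <- length(frames)
  if (nf == 0) stop("no frames read")
  n <- nrow(frames[[1]])
  coords <- array(NA_real_, c(nf, n, 3))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  structure(list(coords = coords, times = times, kinetic = numeric(),
                 potential = numeric(), kinetic_temperature = numeric(),
                 xyz = frames[[nf]], vel = NULL, config = NULL,
                 n_beads = n, table_hash = NA_character_),
            class = "cg_trajectory")
}

# CHARMM DCD: 84-byte control block ("CORD"), title block, natom block,
# then one Fortran record per coordinate component per frame.
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  n <- traj$n_beads
  dt_ps <- if (nf > 1) diff(traj$times[1:2]) else 1
  # AKMA time unit used by CHARMM headers
  delta <- as.numeric(dt_ps / 4.888821e-2)
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  rec(function() {
    writeChar("CORD", con, 4, eos = NULL)
    writeBin(icntrl[1:9], con, size = 4)
    writeBin(delta, con, size = 4)  # stored as float32
    writeBin(icntrl[11:20], con, size = 4)
  }, 84)
  title <- sprintf("%-80s", "cgimm trajectory")
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(n), con, size = 4), 4)
  for (f in seq_len(nf)) {
    for (c in 1:3) {
      rec(function() writeBin(as.numeric(traj$coords[f, , c]), con,
                              size = 4), 4 * n)
    }
  }
  invisible(path)
}

read_dcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_rec <- function() {
    nb <- readBin(con, "integer", 1, size = 4)
    if (length(nb) == 0) return(NULL)
    payload <- readBin(con, "raw", nb)
    if (length(payload) < nb) stop("truncated DCD file")
    nb2 <- readBin(con, "integer", 1, size = 4)
    if (length(nb2) == 0 || nb2 != nb) stop("truncated DCD file")
    payload
  }
  hdr <- rd_rec()
  if (is.null(hdr) || rawToChar(hdr[1:4]) != "CORD") stop("not a DCD file")
  icntrl <- readBin(hdr[5:40], "integer", 9, size = 4)
  nf <- icntrl[1]
  rd_rec() # title
  natom <- readBin(rd_rec(), "integer", 1, size = 4)
  frames <- list()
  for (f in seq_len(nf)) {
    m <- matrix(NA_real_, natom, 3)
    for (c in 1:3) {
      p <- rd_rec()
      if (is.null(p)) stop("truncated DCD file: frame ", f)
      m[, c] <- readBin(p, "numeric", natom, size = 4)
    }
    frames[[f]] <- m
  }
  .traj_from_frames(frames, seq_len(nf))
}
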