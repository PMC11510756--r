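# Trajectory container and text-format interoperability (XYZ and LAMMPS-style
# dump). Coordinates are stored unwrapped; all pair analyses apply the
# minimum-image convention, so chains are always geometrically whole.

new_pa_traj <- function(pos, times, system, params, seq = NULL, dt = NA_real_,
                        potential = NULL, kinetic = NULL) {
  if (length(dim(pos)) != 3) stop("pos must be an n x 3 x frames array")
  if (dim(pos)[3] != length(times)) stop("frame count must match times")
  if (any(diff(times) <= 0) && length(times) > 1)
    stop("times must be strictly increasing")
  structure(list(pos = pos, times = times, charge = system$charge,
                 species = system$species, bonds = system$bonds,
                 box_L = system$box_L, params = params, seq = seq, dt = dt,
                 potential = potential, kinetic = kinetic),
            class = "pa_traj")
}

#' @export
print.pa_traj <- function(x, ...) {
  cat("<pa_traj>", dim(x$pos)[1], "particles,", dim(x$pos)[3], "frames,",
      "t in [", min(x$times), ",", max(x$times), "] tau, box L =",
      x$box_L, "\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$pos)[3]

frame_dt <- function(traj) {
  if (n_frames(traj) < 2) return(NA_real_)
  diff(traj$times[1:2])
}

chain_index <- function(traj, chain) which(traj$species == chain)

frame_coords <- function(traj, idx, f) {
  matrix(traj$pos[idx, , f], ncol = 3)
}

min_image <- function(d, L) {
  if (!is.finite(L) || L <= 0) return(d)
  d - L * round(d / L)
}

#' Center-to-center distance between the two chains, per frame
#'
#' Chain centroids are taken over all monomers with unit mass; coordinates
#' are unwrapped so each chain is whole, and the centroid difference is
#' reduced by the minimum-image convention.
#'
#' @param traj A two-chain `pa_traj`.
#' @return Numeric vector, one distance (sigma) per frame.
#' @export
center_distance <- function(traj) {
  ia <- chain_index(traj, "A")
  ib <- chain_index(traj, "B")
  if (!length(ia) || !length(ib)) stop("trajectory must contain two chains")
  ca <- apply(traj$pos[ia, , , drop = FALSE], c(2, 3), mean)
  cb <- apply(traj$pos[ib, , , drop = FALSE], c(2, 3), mean)
  d <- min_image(ca - cb, traj$box_L)
  sqrt(colSums(d^2))
}

#' Subset a trajectory by frame index
#' @param traj A `pa_traj`.
#' @param frames Integer frame indices to keep.
#' @return A `pa_traj`.
#' @export
subset_frames <- function(traj, frames) {
  traj$pos <- traj$pos[, , frames, drop = FALSE]
  traj$times <- traj$times[frames]
  if (!is.null(traj$potential)) traj$potential <- traj$potential[frames]
  if (!is.null(traj$kinetic)) traj$kinetic <- traj$kinetic[frames]
  traj
}

#' Write a trajectory as extended XYZ text
#'
#' Element column carries the species (`A`/`B`/`I` for counterions); charges
#' are not stored in XYZ (use the dump format to round-trip them).
#'
#' @param traj A `pa_traj`.
#' @param path Output file.
#' @export
write_xyz <- function(traj, path) {
  n <- dim(traj$pos)[1]
  el <- ifelse(traj$species == "ion", "I", traj$species)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(as.character(n),
                 sprintf("time=%.6g box=%.6g", traj$times[f], traj$box_L)), con)
    writeLines(sprintf("%s %.8g %.8g %.8g", el, traj$pos[, 1, f],
                       traj$pos[, 2, f], traj$pos[, 3, f]), con)
  }
  invisible(path)
}

#' Write a trajectory as a LAMMPS-style dump
#'
#' Columns `id type q x y z` with type 1/2 for the two chains and 3 for
#' counterions; this is the lossless text round-trip format.
#'
#' @inheritParams write_xyz
#' @export
write_lammps_dump <- function(traj, path) {
  n <- dim(traj$pos)[1]
  type <- c(A = 1L, B = 2L, ion = 3L)[traj$species]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(c("ITEM: TIMESTEP", sprintf("%.6f", traj$times[f]),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 rep(sprintf("0 %.6f", traj$box_L), 3),
                 "ITEM: ATOMS id type q x y z"), con)
    writeLines(sprintf("%d %d %g %.8g %.8g %.8g", seq_len(n), type,
                       traj$charge, traj$pos[, 1, f], traj$pos[, 2, f],
                       traj$pos[, 3, f]), con)
  }
  invisible(path)
}

read_lammps_dump <- function(path) {
  lines <- readLines(path)
  i <- 1
  frames <- list()
  times <- numeric()
  n_atoms <- NA_integer_
  box_L <- NA_real_
  meta <- NULL
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "ITEM: TIMESTEP"))
      stop("dump format error at line ", i, ": expected ITEM: TIMESTEP")
    tm <- as.numeric(lines[i + 1])
    if (!startsWith(lines[i + 2], "ITEM: NUMBER OF ATOMS"))
      stop("dump format error at line ", i + 2)
    na <- as.integer(lines[i + 3])
    if (!is.na(n_atoms) && na != n_atoms)
      stop("inconsistent atom count at line ", i + 3)
    n_atoms <- na
    bl <- strsplit(trimws(lines[i + 5]), "\\s+")[[1]]
    box_L <- as.numeric(bl[2]) - as.numeric(bl[1])
    hdr <- strsplit(sub("^ITEM: ATOMS\\s*", "", lines[i + 8]), "\\s+")[[1]]
    need <- c("id", "type", "q", "x", "y", "z")
    if (!all(need %in% hdr))
      stop("dump format error at line ", i + 8, ": need columns ",
           paste(need, collapse = " "))
    if (i + 8 + n_atoms > length(lines))
      stop("truncated dump file: last complete frame is ", length(times))
    body <- lines[(i + 9):(i + 8 + n_atoms)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                nrow = n_atoms, byrow = TRUE)
    colnames(m) <- hdr[seq_len(ncol(m))]
    m <- m[order(m[, "id"]), , drop = FALSE]
    if (is.null(meta)) {
      meta <- list(type = as.integer(m[, "type"]), q = m[, "q"])
    }
    frames[[length(frames) + 1]] <- m[, c("x", "y", "z"), drop = FALSE]
    times <- c(times, tm)
    i <- i + 9 + n_atoms
  }
  pos <- array(unlist(frames), dim = c(n_atoms, 3, length(frames)))
  species <- c("A", "B", "ion")[meta$type]
  bonds <- matrix(integer(0), 0, 2)
  for (sp in c("A", "B")) {
    idx <- which(species == sp)
    if (length(idx) > 1) bonds <- rbind(bonds, cbind(idx[-length(idx)], idx[-1]))
  }
  sys <- list(charge = meta$q, species = species, bonds = bonds, box_L = box_L)
  new_pa_traj(pos, times, sys, params = NULL)
}

read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1
  frames <- list(); times <- numeric(); box_L <- Inf; species <- NULL
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("xyz format error at line ", i)
    cm <- lines[i + 1]
    tm <- suppressWarnings(as.numeric(sub(".*time=([0-9.eE+-]+).*", "\\1", cm)))
    bx <- suppressWarnings(as.numeric(sub(".*box=([0-9.eE+-]+).*", "\\1", cm)))
    if (is.finite(bx)) box_L <- bx
    if (i + 1 + n > length(lines))
      stop("truncated xyz file: last complete frame is ", length(times))
    body <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    el <- vapply(body, `[`, character(1), 1)
    xyz <- t(vapply(body, function(b) as.numeric(b[2:4]), numeric(3)))
    if (is.null(species)) species <- ifelse(el == "I", "ion", el)
    frames[[length(frames) + 1]] <- xyz
    times <- c(times, if (is.finite(tm)) tm else length(times))
    i <- i + 2 + n
  }
  pos <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  bonds <- matrix(integer(0), 0, 2)
  for (sp in c("A", "B")) {
    idx <- which(species == sp)
    if (length(idx) > 1) bonds <- rbind(bonds, cbind(idx[-length(idx)], idx[-1]))
  }
  sys <- list(charge = rep(0, nrow(frames[[1]])), species = species,
              bonds = bonds, box_L = box_L)
  new_pa_traj(pos, times, sys, params = NULL)
}

#' Read a trajectory from disk
#'
#' @param path File path.
#' @param format `"native"` (serialized R object, written by
#'   [write_trajectory()]), `"lammps_dump"`, or `"xyz"`.
#' @return A `pa_traj`.
#' @export
read_trajectory <- function(path, format = c("native", "lammps_dump", "xyz")) {
  format <- match.arg(format)
  switch(format,
         native = {
           x <- readRDS(path)
           if (!inherits(x, "pa_traj")) stop("not a pa_traj file")
           x
         },
         lammps_dump = read_lammps_dump(path),
         xyz = read_xyz(path))
}

#' Write a trajectory to disk
#'
#' @param traj A `pa_traj`.
#' @param path Output path.
#' @param format See [read_trajectory()].
#' @export
write_trajectory <- function(traj, path,
                             format = c("native", "lammps_dump", "xyz")) {
  format <- match.arg(format)
  switch(format,
         native = saveRDS(traj, path),
         lammps_dump = write_lammps_dump(traj, path),
         xyz = write_xyz(traj, path))
  invisible(path)
}
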