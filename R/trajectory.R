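# Particle configurations and trajectories.
#
# Positions are in nm, times in ps, masses in amu; boxes are orthorhombic
# (edge vector of length 3, nm). These are deliberately lightweight base-R
# containers: frames are plain numeric matrices, so the analysis code and the
# brute-force test oracles can share them without conversion.

#' Create a single particle configuration
#'
#' @param positions numeric matrix (n x 3), coordinates in nm.
#' @param box numeric length-3 vector of orthorhombic box edges in nm.
#' @param species character vector of species labels (recycled if length 1);
#'   defaults to `"X"`.
#' @param masses numeric vector of atomic masses in amu (recycled if length
#'   1); defaults to 1. Used for centre-of-mass work.
#' @return an object of class `kb_config`.
#' @export
kb_config <- function(positions, box, species = "X", masses = 1) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L || !is.numeric(positions)) {
    stop("`positions` must be a numeric n x 3 matrix", call. = FALSE)
  }
  if (any(!is.finite(positions))) {
    stop("all positions must be finite", call. = FALSE)
  }
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    stop("`box` must be three positive finite edge lengths (nm)",
         call. = FALSE)
  }
  n <- nrow(positions)
  species <- rep_len(as.character(species), n)
  masses <- rep_len(as.numeric(masses), n)
  if (any(masses <= 0)) stop("masses must be positive", call. = FALSE)
  structure(
    list(positions = positions, box = as.numeric(box),
         species = species, masses = masses),
    class = "kb_config"
  )
}

#' Create a trajectory from one or more configurations
#'
#' @param frames a `kb_config` or a list of them; particle count and species
#'   labels must be constant across frames.
#' @param times optional numeric vector of frame times in ps.
#' @return an object of class `kb_trajectory`.
#' @export
kb_trajectory <- function(frames, times = NULL) {
  if (inherits(frames, "kb_config")) frames <- list(frames)
  if (!is.list(frames) || length(frames) < 1L ||
      !all(vapply(frames, inherits, logical(1), "kb_config"))) {
    stop("`frames` must be a non-empty list of kb_config objects",
         call. = FALSE)
  }
  n0 <- nrow(frames[[1L]]$positions)
  sp0 <- frames[[1L]]$species
  for (f in frames) {
    if (nrow(f$positions) != n0 || !identical(f$species, sp0)) {
      stop("particle count and species labels must be constant across frames",
           call. = FALSE)
    }
  }
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames)) {
    stop("`times` must have one entry per frame", call. = FALSE)
  }
  structure(list(frames = frames, times = as.numeric(times)),
            class = "kb_trajectory")
}

#' @export
print.kb_trajectory <- function(x, ...) {
  f1 <- x$frames[[1L]]
  cat(sprintf("kb_trajectory: %d frame(s), %d particles, box %s nm\n",
              length(x$frames), nrow(f1$positions),
              paste(signif(f1$box, 4), collapse = " x ")))
  cat("species:", paste(names(table(f1$species)),
                        table(f1$species), collapse = ", "), "\n")
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Resolve an atom selection to integer indices
#'
#' Selections may be integer indices, a logical mask, or a character vector
#' of species labels (all atoms whose label matches).
#'
#' @param traj a `kb_trajectory` or `kb_config`.
#' @param sel integer, logical or character selection.
#' @return sorted integer vector of atom indices.
#' @export
select_atoms <- function(traj, sel) {
  cfg <- if (inherits(traj, "kb_trajectory")) traj$frames[[1L]] else traj
  n <- nrow(cfg$positions)
  if (is.character(sel)) {
    idx <- which(cfg$species %in% sel)
  } else if (is.logical(sel)) {
    if (length(sel) != n) stop("logical selection has wrong length",
                               call. = FALSE)
    idx <- which(sel)
  } else if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (any(idx < 1L) || any(idx > n)) {
      stop("selection indices out of range", call. = FALSE)
    }
  } else {
    stop("unsupported selection type", call. = FALSE)
  }
  idx <- sort(unique(idx))
  if (length(idx) == 0L) stop("selection is empty", call. = FALSE)
  idx
}

# Mass-weighted centre of mass of a group of atoms, unwrapped with respect to
# the group's first atom so that periodic images do not split the group.
group_com <- function(cfg, idx) {
  pos <- cfg$positions[idx, , drop = FALSE]
  ref <- pos[1L, ]
  d <- sweep(pos, 2L, ref)
  d <- min_image(d, cfg$box)
  m <- cfg$masses[idx]
  ref + colSums(d * m) / sum(m)
}

#' Write a trajectory as a (multi-model) GRO file
#'
#' One GRO block per frame, concatenated; species labels are used as both
#' residue and atom names. Coordinates in nm, standard `%8.3f` fields.
#'
#' @param traj a `kb_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(traj$frames)) {
    cfg <- traj$frames[[fi]]
    n <- nrow(cfg$positions)
    writeLines(sprintf("kbsolv frame t=%.3f ps", traj$times[fi]), con)
    writeLines(sprintf("%5d", n), con)
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     rep(1L, n), substr(cfg$species, 1, 5),
                     substr(cfg$species, 1, 5), seq_len(n) %% 100000L,
                     cfg$positions[, 1], cfg$positions[, 2],
                     cfg$positions[, 3])
    writeLines(lines, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       cfg$box[1], cfg$box[2], cfg$box[3]), con)
  }
  invisible(path)
}

#' Read a (multi-model) GRO file written by [write_gro()]
#'
#' @param path input file path.
#' @param masses atom masses in amu (recycled); GRO carries none.
#' @return a `kb_trajectory`.
#' @export
read_gro <- function(path, masses = 1) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric(0)
  i <- 1L
  while (i <= length(lines)) {
    title <- lines[i]
    n <- as.integer(trimws(lines[i + 1L]))
    atom_lines <- lines[(i + 2L):(i + 1L + n)]
    pos <- matrix(NA_real_, n, 3L)
    species <- character(n)
    for (a in seq_len(n)) {
      ln <- atom_lines[a]
      species[a] <- trimws(substr(ln, 11, 15))
      pos[a, ] <- as.numeric(c(substr(ln, 21, 28), substr(ln, 29, 36),
                               substr(ln, 37, 44)))
    }
    box <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1L]])[1:3]
    frames[[length(frames) + 1L]] <- kb_config(pos, box, species, masses)
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times <- c(times, if (length(tm)) as.numeric(sub("t=\\s*", "", tm))
               else length(times))
    i <- i + 3L + n
  }
  kb_trajectory(frames, times)
}

#' Write a trajectory as a multi-frame XYZ file
#'
#' Coordinates are written in nm (the package's native unit), with the box
#' recorded on the comment line.
#'
#' @param traj a `kb_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(traj$frames)) {
    cfg <- traj$frames[[fi]]
    n <- nrow(cfg$positions)
    writeLines(as.character(n), con)
    writeLines(sprintf("box %.6f %.6f %.6f nm t=%.3f ps",
                       cfg$box[1], cfg$box[2], cfg$box[3], traj$times[fi]),
               con)
    writeLines(sprintf("%-6s %12.6f %12.6f %12.6f", cfg$species,
                       cfg$positions[, 1], cfg$positions[, 2],
                       cfg$positions[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file written by [write_xyz()]
#'
#' @param path input file path.
#' @param masses atom masses in amu (recycled).
#' @return a `kb_trajectory`.
#' @export
read_xyz <- function(path, masses = 1) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric(0)
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(trimws(lines[i]))
    comment <- lines[i + 1L]
    toks <- strsplit(trimws(comment), "\\s+")[[1L]]
    box <- as.numeric(toks[2:4])
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    species <- vapply(parts, `[[`, character(1), 1L)
    pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- kb_config(pos, box, species, masses)
    tm <- regmatches(comment, regexpr("t=\\s*[-0-9.eE+]+", comment))
    times <- c(times, if (length(tm)) as.numeric(sub("t=\\s*", "", tm))
               else length(times))
    i <- i + 2L + n
  }
  kb_trajectory(frames, times)
}
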