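#' Read a LAMMPS text dump into a trajectory
#'
#' Parses the `ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS / ATOMS`
#' dialect. Atoms are re-sorted by id, the orthorhombic box is read from the
#' bounds block (triclinic boxes are rejected), positions are wrapped into
#' `[0, L)` and species are taken from the `type` column, re-indexed densely
#' from 0 preserving numeric order; the original type labels are kept in
#' metadata for write-back. Image-flag columns (`ix iy iz`) are accepted and
#' discarded with a notice.
#'
#' @param path Dump file path (or connection-readable text file).
#' @param column_map Optional named vector mapping the roles `id`, `type`,
#'   `x`, `y`, `z`, `vx`, `vy`, `vz` to column names in the file's ATOMS
#'   header; defaults to same-named columns.
#' @param cond Optional [condition()] to attach.
#' @return A [trajectory()].
#' @export
read_lammps_dump <- function(path, column_map = NULL, cond = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty dump stream")
  starts <- grep("^ITEM: TIMESTEP", lines)
  if (length(starts) == 0) stop("no complete frame found in dump stream")
  ends <- c(starts[-1] - 1L, length(lines))
  n_atoms_ref <- NULL
  type_levels <- NULL
  snaps <- lapply(seq_along(starts), function(fi) {
    fl <- lines[starts[fi]:ends[fi]]
    timestep <- as.numeric(fl[2])
    if (!grepl("^ITEM: NUMBER OF ATOMS", fl[3]))
      stop(sprintf("frame %d: missing NUMBER OF ATOMS item", fi))
    n <- as.integer(fl[4])
    if (!is.null(n_atoms_ref) && n != n_atoms_ref)
      stop(sprintf("frame %d: atom count %d differs from first frame %d",
                   fi, n, n_atoms_ref))
    n_atoms_ref <<- n
    bounds_hdr <- fl[5]
    if (!grepl("^ITEM: BOX BOUNDS", bounds_hdr))
      stop(sprintf("frame %d: missing BOX BOUNDS item", fi))
    if (grepl("xy|xz|yz", bounds_hdr))
      stop(sprintf("frame %d: triclinic boxes are not supported", fi))
    bounds <- do.call(rbind, lapply(fl[6:8], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    if (ncol(bounds) != 2)
      stop(sprintf("frame %d: triclinic boxes are not supported", fi))
    lo <- bounds[, 1]; hi <- bounds[, 2]
    box <- hi - lo
    atoms_hdr <- fl[9]
    if (!grepl("^ITEM: ATOMS", atoms_hdr))
      stop(sprintf("frame %d: missing ATOMS item", fi))
    cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", atoms_hdr), "\\s+")[[1]]
    cmap <- c(id = "id", type = "type", x = "x", y = "y", z = "z",
              vx = "vx", vy = "vy", vz = "vz")
    if (!is.null(column_map)) cmap[names(column_map)] <- column_map
    need <- c("id", "type", "x", "y", "z")
    missing_cols <- need[!cmap[need] %in% cols]
    if (length(missing_cols) > 0)
      stop(sprintf("frame %d: required column(s) %s absent from ATOMS header",
                   fi, paste(cmap[missing_cols], collapse = ", ")))
    if (any(c("ix", "iy", "iz") %in% cols))
      message("image-flag columns present; discarded (wrapped coordinates suffice)")
    dat <- utils::read.table(text = fl[10:(9 + n)], col.names = cols,
                             check.names = FALSE)
    dat <- dat[order(dat[[cmap["id"]]]), , drop = FALSE]
    has_vel <- all(cmap[c("vx", "vy", "vz")] %in% cols)
    pos <- as.matrix(dat[, cmap[c("x", "y", "z")]])
    pos <- sweep(pos, 2, lo, `-`)  # box origin to 0
    raw_type <- dat[[cmap["type"]]]
    type_levels <<- sort(unique(c(type_levels, raw_type)))
    vel <- if (has_vel) as.matrix(dat[, cmap[c("vx", "vy", "vz")]]) else NULL
    list(pos = pos, vel = vel, raw_type = raw_type, box = box,
         timestep = timestep)
  })
  frames <- lapply(snaps, function(s) {
    species <- match(s$raw_type, type_levels) - 1L
    sn <- snapshot(s$pos, s$vel, species, s$box, time = s$timestep,
                   condition = cond)
    sn$has_velocities <- !is.null(s$vel)
    sn
  })
  tr <- trajectory(cond, frames,
                   sample_interval = if (length(frames) > 1)
                     frames[[2]]$time - frames[[1]]$time else NA_real_)
  attr(tr, "type_labels") <- type_levels
  tr
}

fmt_num <- function(x, precision) {
  sprintf(paste0("%.", precision, "g"), x)
}

# Format positions so the printed value, once re-read, still lies in
# [0, L): a coordinate that rounds up to exactly L is wrapped to 0 first.
fmt_pos <- function(x, box_edge, precision) {
  s <- fmt_num(x, precision)
  bad <- as.numeric(s) >= box_edge
  if (any(bad)) s[bad] <- fmt_num(as.numeric(s[bad]) - box_edge, precision)
  s
}

#' Write a trajectory as a LAMMPS text dump
#'
#' Inverse of [read_lammps_dump()] at the stated precision: columns
#' `id type x y z vx vy vz`, periodic bounds `0 .. L`.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param precision Significant digits written.
#' @return `path`, invisibly.
#' @export
write_lammps_dump <- function(traj, path, precision = 10) {
  type_labels <- attr(traj, "type_labels")
  con <- file(path, "w")
  on.exit(close(con))
  for (snap in traj$snapshots) {
    n <- nrow(snap$positions)
    types <- if (!is.null(type_labels)) type_labels[snap$species + 1L]
             else snap$species + 1L
    writeLines(c(
      "ITEM: TIMESTEP", fmt_num(snap$time, precision),
      "ITEM: NUMBER OF ATOMS", as.character(n),
      "ITEM: BOX BOUNDS pp pp pp",
      vapply(1:3, function(k) paste("0", fmt_num(snap$box[k], precision)),
             character(1)),
      "ITEM: ATOMS id type x y z vx vy vz"
    ), con)
    body <- vapply(seq_len(n), function(i) paste(
      i, types[i],
      paste(vapply(1:3, function(k)
        fmt_pos(snap$positions[i, k], snap$box[k], precision), character(1)),
        collapse = " "),
      paste(fmt_num(snap$velocities[i, ], precision), collapse = " ")
    ), character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read an extended XYZ trajectory
#'
#' The comment line must carry a `Lattice="..."` field (only diagonal,
#' orthorhombic lattices are accepted) and a `Properties=` field with
#' `species` and `pos`; velocities (`vel`) are optional and their absence
#' yields a flagged zero-velocity snapshot.
#'
#' @param path Extended XYZ file path.
#' @param cond Optional [condition()] to attach.
#' @return A [trajectory()].
#' @export
read_extxyz <- function(path, cond = NULL) {
  lines <- readLines(path)
  i <- 1L
  snaps <- list()
  type_levels <- NULL
  fi <- 0L
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    fi <- fi + 1L
    n <- as.integer(trimws(lines[i]))
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]][2]
    if (is.na(lat)) stop(sprintf("frame %d: missing Lattice field", fi))
    lv <- as.numeric(strsplit(trimws(lat), "\\s+")[[1]])
    if (length(lv) != 9) stop(sprintf("frame %d: malformed Lattice", fi))
    lmat <- matrix(lv, 3, 3, byrow = TRUE)
    if (any(abs(lmat[upper.tri(lmat) | lower.tri(lmat)]) > 1e-12))
      stop(sprintf("frame %d: non-orthorhombic lattice rejected", fi))
    box <- diag(lmat)
    props <- regmatches(comment,
                        regexec("Properties=([^ ]+)", comment))[[1]][2]
    if (is.na(props)) stop(sprintf("frame %d: missing Properties field", fi))
    fields <- strsplit(props, ":")[[1]]
    fnames <- fields[seq(1, length(fields), by = 3)]
    fwidth <- as.integer(fields[seq(3, length(fields), by = 3)])
    tval <- regmatches(comment, regexec("Time=([0-9eE+.-]+)", comment))[[1]][2]
    dat <- utils::read.table(text = lines[(i + 2L):(i + 1L + n)])
    col0 <- cumsum(c(0, fwidth))
    getblk <- function(nm) {
      j <- match(nm, fnames)
      if (is.na(j)) return(NULL)
      as.matrix(dat[, col0[j] + seq_len(fwidth[j]), drop = FALSE])
    }
    if (!("species" %in% fnames) || !("pos" %in% fnames))
      stop(sprintf("frame %d: Properties must include species and pos", fi))
    jsp <- match("species", fnames)
    raw_sp <- as.character(dat[[col0[jsp] + 1L]])
    type_levels <- sort(unique(c(type_levels, raw_sp)))
    snaps[[fi]] <- list(pos = getblk("pos"), vel = getblk("vel"),
                        raw = raw_sp, box = box,
                        time = if (is.na(tval)) fi - 1 else as.numeric(tval))
    i <- i + 2L + n
  }
  if (length(snaps) == 0) stop("no frames found in extxyz stream")
  frames <- lapply(snaps, function(s) {
    species <- match(s$raw, type_levels) - 1L
    sn <- snapshot(s$pos, s$vel, species, s$box, time = s$time,
                   condition = cond)
    sn$has_velocities <- !is.null(s$vel)
    sn
  })
  tr <- trajectory(cond, frames)
  attr(tr, "type_labels") <- type_levels
  tr
}

#' Write a trajectory as extended XYZ
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param precision Significant digits written.
#' @param write_velocities Include the velocity block.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(traj, path, precision = 10,
                         write_velocities = TRUE) {
  type_labels <- attr(traj, "type_labels")
  con <- file(path, "w")
  on.exit(close(con))
  for (snap in traj$snapshots) {
    n <- nrow(snap$positions)
    sp <- if (!is.null(type_labels)) type_labels[snap$species + 1L]
          else paste0("S", snap$species)
    lat <- sprintf('Lattice="%s 0 0 0 %s 0 0 0 %s"',
                   fmt_num(snap$box[1], precision),
                   fmt_num(snap$box[2], precision),
                   fmt_num(snap$box[3], precision))
    props <- if (write_velocities) "Properties=species:S:1:pos:R:3:vel:R:3"
             else "Properties=species:S:1:pos:R:3"
    writeLines(c(as.character(n),
                 paste(lat, props,
                       sprintf("Time=%s", fmt_num(snap$time, precision)))),
               con)
    body <- vapply(seq_len(n), function(i) {
      row <- paste(sp[i],
                   paste(vapply(1:3, function(k)
                     fmt_pos(snap$positions[i, k], snap$box[k], precision),
                     character(1)), collapse = " "))
      if (write_velocities)
        row <- paste(row,
                     paste(fmt_num(snap$velocities[i, ], precision),
                           collapse = " "))
      row
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

ARCHIVE_VERSION <- "pointrdf-archive-1"

#' Save / load a dataset archive of trajectories
#'
#' Lossless native-precision container (versioned RDS) for a collection of
#' trajectories keyed by condition id. A version mismatch on load is refused
#' with both versions reported.
#'
#' @param trajectories Named list of [trajectory()] objects (may be empty).
#' @param path Archive path.
#' @param units Unit-system tag stored in the archive.
#' @return `path` invisibly (save); the named trajectory list, with the
#'   archive metadata in attributes (load).
#' @export
save_archive <- function(trajectories, path, units = "reduced") {
  ids <- names(trajectories)
  if (length(trajectories) > 0 &&
      (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))))
    stop("trajectories must be uniquely named by condition_id")
  saveRDS(list(version = ARCHIVE_VERSION, units = units,
               trajectories = trajectories),
          path)
  invisible(path)
}

#' @rdname save_archive
#' @export
load_archive <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, ARCHIVE_VERSION))
    stop(sprintf("archive version mismatch: file has %s, reader expects %s",
                 obj$version, ARCHIVE_VERSION))
  structure(obj$trajectories, units = obj$units, version = obj$version)
}
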