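#' Construct a trajectory ensemble
#'
#' A `TrajectoryEnsemble` holds one or more replicas of Cartesian frames
#' (nm) over a fixed atom set, with per-frame timestamps in ps.
#'
#' @param coords list of 3-d arrays, one per replica, each with
#'   `dim = c(n_atoms, 3, n_frames)`.
#' @param times list of numeric vectors (ps), strictly increasing within a
#'   replica, one per replica.
#' @param merged_from optional metadata recorded by [merge_replicas()]:
#'   `list(replica_sizes = <frames retained per source replica>)`.
#' @return object of class `TrajectoryEnsemble`.
#' @export
trajectory_ensemble <- function(coords, times, merged_from = NULL) {
  stopifnot(is.list(coords), is.list(times), length(coords) == length(times))
  if (length(coords) == 0L)
    trj_error("trajcomm_empty_error", "ensemble needs at least one replica")
  na <- dim(coords[[1]])[1]
  for (k in seq_along(coords)) {
    d <- dim(coords[[k]])
    if (length(d) != 3L || d[2] != 3L)
      trj_error("trajcomm_shape_error", "replica %d: coords must be (atoms, 3, frames)", k)
    if (d[1] != na)
      trj_error("trajcomm_shape_error", "replica %d: atom count %d != %d", k, d[1], na)
    if (d[3] == 0L)
      trj_error("trajcomm_empty_error", "replica %d has zero frames", k)
    if (length(times[[k]]) != d[3])
      trj_error("trajcomm_shape_error", "replica %d: %d timestamps for %d frames",
                k, length(times[[k]]), d[3])
    if (d[3] > 1L && any(diff(times[[k]]) <= 0))
      trj_error("trajcomm_integrity_error", "replica %d: timestamps not strictly increasing", k)
  }
  structure(list(coords = coords, times = times, n_atoms = na,
                 merged_from = merged_from),
            class = "TrajectoryEnsemble")
}

#' @export
print.TrajectoryEnsemble <- function(x, ...) {
  cat(sprintf("TrajectoryEnsemble: %d replica(s), frames %s, %d atoms\n",
              length(x$coords),
              paste(vapply(x$coords, function(c) dim(c)[3], 1L), collapse = "+"),
              x$n_atoms))
  invisible(x)
}

n_replicas <- function(ens) length(ens$coords)
replica_frames <- function(ens) vapply(ens$coords, function(c) dim(c)[3], 1L)
total_frames <- function(ens) sum(replica_frames(ens))

# all frames of all replicas as one (atoms, 3, frames) array, replica order
flat_coords <- function(ens) {
  if (n_replicas(ens) == 1L) return(ens$coords[[1]])
  array(unlist(ens$coords, use.names = FALSE),
        dim = c(ens$n_atoms, 3, total_frames(ens)))
}

flat_times <- function(ens) unlist(ens$times, use.names = FALSE)

#' Read trajectories from disk
#'
#' One replica per input file. The implemented dialect is the documented
#' plain-text internal format (see [write_trajectory()]); binary DCD/XTC
#' adapters can be registered under the same signature but are not bundled.
#'
#' @param paths character vector of file paths.
#' @param structure `StructureModel` the frames must match.
#' @param stride_ps if the file carries no timestamps, synthesize
#'   `0, stride_ps, 2*stride_ps, ...`.
#' @return `TrajectoryEnsemble` with one replica per file.
#' @export
load_trajectory <- function(paths, structure, stride_ps = 1) {
  coords <- list(); times <- list()
  for (p in paths) {
    r <- read_trj_text(p, stride_ps)
    if (dim(r$coords)[1] != n_atoms(structure))
      trj_error("trajcomm_shape_error", "%s: %d atoms, structure has %d",
                p, dim(r$coords)[1], n_atoms(structure))
    coords <- c(coords, list(r$coords)); times <- c(times, list(r$times))
  }
  trajectory_ensemble(coords, times)
}

#' Write a trajectory replica as plain text
#'
#' Format: a header `# trajcomm trj v1`, `natoms N`, `frames F`; then per
#' frame a line `time_ps T` followed by `N` lines of `x y z` in nm at
#' full double precision. Lossless round trip.
#'
#' @param ens `TrajectoryEnsemble`.
#' @param path output path (single replica) or vector of paths, one per replica.
#' @export
write_trajectory <- function(ens, path) {
  stopifnot(length(path) == n_replicas(ens))
  for (k in seq_len(n_replicas(ens))) {
    co <- ens$coords[[k]]; nf <- dim(co)[3]
    con <- file(path[k], "w")
    writeLines(c("# trajcomm trj v1",
                 sprintf("natoms %d", dim(co)[1]),
                 sprintf("frames %d", nf)), con)
    for (i in seq_len(nf)) {
      writeLines(sprintf("time_ps %.17g", ens$times[[k]][i]), con)
      writeLines(sprintf("%.17g %.17g %.17g", co[, 1, i], co[, 2, i], co[, 3, i]), con)
    }
    close(con)
  }
  invisible(path)
}

read_trj_text <- function(path, stride_ps = 1) {
  if (!file.exists(path)) trj_error("trajcomm_io_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  hdr <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    if (is.na(ln)) trj_error("trajcomm_format_error", "%s: missing '%s' header", path, key)
    as.numeric(sub(paste0("^", key, " "), "", ln))
  }
  na <- as.integer(hdr("natoms")); nf <- as.integer(hdr("frames"))
  if (nf == 0L) trj_error("trajcomm_empty_error", "%s: zero frames", path)
  body <- lines[-(1:2)]
  tlines <- grep("^time_ps", body)
  has_time <- length(tlines) == nf
  co <- array(NA_real_, dim = c(na, 3, nf))
  times <- numeric(nf)
  pos <- 1L
  for (i in seq_len(nf)) {
    if (has_time) {
      times[i] <- as.numeric(sub("^time_ps ", "", body[pos])); pos <- pos + 1L
    } else times[i] <- (i - 1) * stride_ps
    block <- body[pos:(pos + na - 1L)]
    m <- matrix(scan(text = block, quiet = TRUE), ncol = 3, byrow = TRUE)
    if (nrow(m) != na || anyNA(m))
      trj_error("trajcomm_format_error", "%s: bad coordinate block in frame %d", path, i)
    co[, , i] <- m
    pos <- pos + na
  }
  list(coords = co, times = times)
}

#' Discard the relaxation head of each replica and concatenate
#'
#' Reproduces the standard production-analysis preprocessing: drop the first
#' `discard_head_ns` of every replica (relaxation) and merge the retained
#' frames into a single replica, recording the original replica boundaries so
#' convergence analysis can split the merged trajectory into per-replica
#' halves.
#'
#' @param ens `TrajectoryEnsemble`.
#' @param discard_head_ns duration in ns removed from the start of each replica.
#' @return single-replica `TrajectoryEnsemble` with `merged_from` metadata.
#' @export
merge_replicas <- function(ens, discard_head_ns = 0) {
  keep <- list(); kept_t <- list()
  for (k in seq_len(n_replicas(ens))) {
    t <- ens$times[[k]]
    sel <- which(t - t[1] >= discard_head_ns * 1000)
    if (length(sel) == 0L)
      trj_error("trajcomm_empty_error",
                "replica %d: discarding %g ns leaves no frames", k, discard_head_ns)
    keep[[k]] <- ens$coords[[k]][, , sel, drop = FALSE]
    kept_t[[k]] <- t[sel]
  }
  sizes <- vapply(keep, function(c) dim(c)[3], 1L)
  co <- array(unlist(keep, use.names = FALSE), dim = c(ens$n_atoms, 3, sum(sizes)))
  # re-base times so the merged series is strictly increasing and continuous
  out_t <- numeric(0); offset <- 0
  for (k in seq_along(kept_t)) {
    tt <- kept_t[[k]] - kept_t[[k]][1]
    out_t <- c(out_t, tt + offset)
    dt <- if (length(tt) > 1) tt[2] - tt[1] else 1
    offset <- offset + tt[length(tt)] + dt
  }
  trajectory_ensemble(list(co), list(out_t),
                      merged_from = list(replica_sizes = sizes))
}

#' Duration of each replica in ns
#' @param ens `TrajectoryEnsemble`.
#' @return numeric vector, ns.
#' @export
replica_duration_ns <- function(ens) {
  vapply(ens$times, function(t) (t[length(t)] - t[1]) / 1000, 1)
}
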