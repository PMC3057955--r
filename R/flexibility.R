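#' Classify arginine side-chain rotamers from chi dihedrals
#'
#' Maps (chi1, chi2, chi3, chi4) dihedral angles onto named rotamer bins.
#' chi1-chi3 use the p/t/m convention (modal values 60, 180 and 300
#' degrees) with half-open 120-degree bins: p = \[0, 120), t = \[120, 240),
#' m = \[240, 360). chi4 maps onto the guanido descriptors "85"
#' (\[0, 120)), "180" (\[120, 240)) and "-85" (\[240, 360)). Angles are
#' wrapped into \[0, 360) first, so adding any multiple of 360 leaves the
#' label unchanged.
#'
#' @param chi Numeric length-4 vector, or an n x 4 matrix / data frame of
#'   per-frame dihedrals in degrees.
#' @return Character vector of labels such as `"mtm180"`.
#' @examples
#' classify_rotamer(c(300, 180, 300, 180))  # "mtm180"
#' classify_rotamer(c(60, 180, 180, 180))   # "ptt180"
#' @export
classify_rotamer <- function(chi) {
  m <- if (is.null(dim(chi))) matrix(as.numeric(chi), ncol = 4L) else
    as.matrix(chi)
  if (ncol(m) != 4L) stop("'chi' must have 4 dihedral columns", call. = FALSE)
  if (!all(is.finite(m))) stop("dihedral angles must be finite", call. = FALSE)
  m <- m %% 360
  bin <- function(x) findInterval(x, c(0, 120, 240))
  ptm <- c("p", "t", "m")
  chi4 <- c("85", "180", "-85")
  paste0(ptm[bin(m[, 1L])], ptm[bin(m[, 2L])], ptm[bin(m[, 3L])],
         chi4[bin(m[, 4L])])
}

#' Rotamer occupancy and transition statistics of a dihedral trace
#'
#' Labels every frame with [classify_rotamer()] and summarises the trace:
#' occupancy fraction per rotamer, number of rotamer changes between
#' consecutive frames, and the dwell-length distribution.
#'
#' @param chi n x 4 matrix (or data frame) of per-frame dihedrals, degrees.
#' @param time Optional per-frame times (ps), stored with the result.
#' @return An object of class `"rotamer_assignment"`: `labels` (per
#'   frame), `occupancy` (named fractions, summing to 1, sorted
#'   decreasing), `transitions` (count), `dwell` (data frame of rotamer
#'   and run length) and `n_frames`.
#' @export
rotamer_statistics <- function(chi, time = NULL) {
  labels <- classify_rotamer(chi)
  n <- length(labels)
  if (n < 2L) stop("need at least 2 frames", call. = FALSE)
  occ <- sort(table(labels) / n, decreasing = TRUE)
  runs <- rle(labels)
  structure(list(
    labels = labels,
    occupancy = stats::setNames(as.numeric(occ), names(occ)),
    transitions = length(runs$lengths) - 1L,
    dwell = data.frame(rotamer = runs$values, length = runs$lengths),
    n_frames = n,
    time = time
  ), class = "rotamer_assignment")
}

#' @export
print.rotamer_assignment <- function(x, ...) {
  cat("Rotamer assignment: ", x$n_frames, " frames, ",
      x$transitions, " transitions\n", sep = "")
  occ <- x$occupancy
  for (i in seq_along(occ))
    cat(sprintf("  %-8s %6.3f\n", names(occ)[i], occ[i]))
  invisible(x)
}

#' Salt-bridge occupancy of a donor-acceptor distance trace
#'
#' Fraction of frames in which the distance is below a cutoff; an intact
#' arginine-carboxylate salt-bridge sits below ~4 A, a broken one near
#' 6 A.
#'
#' @param d Distances, Angstrom (positive).
#' @param cutoff Contact cutoff, Angstrom.
#' @return A list with `occupancy` (fraction of frames with d < cutoff),
#'   `mean_d`, `max_d` and `n_frames`.
#' @examples
#' salt_bridge_occupancy(c(3.1, 3.4, 5.9))
#' @export
salt_bridge_occupancy <- function(d, cutoff = 4.0) {
  d <- as.numeric(d)
  if (length(d) == 0L) stop("empty distance trace", call. = FALSE)
  if (any(d <= 0)) stop("distances must be positive", call. = FALSE)
  list(occupancy = mean(d < cutoff), mean_d = mean(d), max_d = max(d),
       n_frames = length(d))
}

#' Optimal rigid-body superposition of two coordinate sets
#'
#' Kabsch algorithm: least-squares rotation and translation mapping
#' `mobile` onto `reference` via SVD of the cross-covariance of the
#' centred coordinates, with the determinant sign corrected so the result
#' is a proper rotation (no reflection).
#'
#' @param mobile,reference n x 3 coordinate matrices (same n, n >= 3),
#'   Angstrom.
#' @return A list with `rotation` (3 x 3, applied on the right to centred
#'   row coordinates), `translation` (length 3), `rmsd` (Angstrom) and
#'   `aligned` (the transformed mobile coordinates).
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' kabsch_superpose(a, a)$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("'mobile' and 'reference' must be equal-sized n x 3 matrices",
         call. = FALSE)
  if (nrow(mobile) < 3L) stop("need at least 3 atoms", call. = FALSE)

  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  sv_check <- svd(A)$d
  if (sv_check[2] < 1e-10 * max(sv_check[1], 1))
    stop("degenerate (collinear) geometry: rotation is not determined",
         call. = FALSE)

  H <- crossprod(A, B)               # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)   # right-multiplication form
  aligned <- A %*% R
  rmsd <- sqrt(mean(rowSums((aligned - B)^2)))
  list(rotation = R,
       translation = cr - drop(cm %*% R),
       rmsd = rmsd,
       aligned = sweep(aligned, 2, cr, `+`))
}

# coerce a frames x atoms x 3 array or list of n x 3 matrices to a list
.ensemble_frames <- function(ensemble) {
  if (is.list(ensemble)) {
    frames <- lapply(ensemble, as.matrix)
  } else if (is.array(ensemble) && length(dim(ensemble)) == 3L) {
    frames <- lapply(seq_len(dim(ensemble)[1L]),
                     function(i) ensemble[i, , , drop = TRUE])
  } else stop("ensemble must be a list of n x 3 matrices or a 3D array",
              call. = FALSE)
  natm <- unique(vapply(frames, nrow, 1L))
  if (length(natm) != 1L)
    stop("inconsistent atom count across frames", call. = FALSE)
  frames
}

#' RMSD of every frame from a reference frame
#'
#' Superposes each frame of an ensemble onto a reference frame with
#' [kabsch_superpose()] and reports the per-frame RMSD. A trajectory is
#' flagged as stable when every value stays below `stable_cutoff`
#' (default 1.5 Angstrom, the usual drift criterion for a well-behaved
#' simulation).
#'
#' @param ensemble List of n x 3 coordinate matrices, or a
#'   frames x atoms x 3 array.
#' @param reference Index of the reference frame (default 1, the start).
#' @param stable_cutoff Stability threshold, Angstrom.
#' @return Numeric vector of RMSDs with attribute `stable` (logical).
#' @export
rmsd_series <- function(ensemble, reference = 1L, stable_cutoff = 1.5) {
  frames <- .ensemble_frames(ensemble)
  stopifnot(reference >= 1L, reference <= length(frames))
  ref <- frames[[reference]]
  out <- vapply(frames, function(f) kabsch_superpose(f, ref)$rmsd, 0)
  attr(out, "stable") <- all(out < stable_cutoff)
  out
}

#' Per-atom root-mean-square fluctuation of an ensemble
#'
#' Two-pass iterative superposition: frames are first aligned to the
#' initial frame and averaged; all frames are then re-aligned to that mean
#' structure and the mean recomputed. The RMSF of each atom is the square
#' root of its time-averaged squared deviation from the final mean.
#' Rigid-body motion of the whole ensemble therefore contributes nothing.
#'
#' @param ensemble List of n x 3 coordinate matrices, or a
#'   frames x atoms x 3 array (>= 2 frames).
#' @return Numeric vector of per-atom RMSF values, Angstrom.
#' @export
rmsf_per_atom <- function(ensemble) {
  frames <- .ensemble_frames(ensemble)
  if (length(frames) < 2L) stop("need at least 2 frames", call. = FALSE)
  ref <- frames[[1L]]
  for (pass in 1:2) {
    aligned <- lapply(frames, function(f) kabsch_superpose(f, ref)$aligned)
    ref <- Reduce(`+`, aligned) / length(aligned)
  }
  dev2 <- lapply(aligned, function(f) rowSums((f - ref)^2))
  sqrt(Reduce(`+`, dev2) / length(dev2))
}
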