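#' Dose grid constructor
#'
#' A 3-D scalar dose field on a regular grid. Arrays are stored with
#' `dim = c(nx, ny, nz)` in R's column-major order (x fastest), where
#' x = lateral (+x towards the patient's left), y = anterior--posterior
#' (+y posterior) and z = inferior--superior (+z superior). All grids of one
#' patient share this geometry; doses are Gy, lengths mm.
#'
#' @param values numeric 3-D array of nonnegative doses (Gy).
#' @param spacing isotropic voxel spacing, mm.
#' @param origin physical coordinate (mm) of the centre of voxel `[1,1,1]`.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("dose values must be finite and >= 0")
  }
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("dose_grid:", paste(dim(x$values), collapse = "x"), "voxels @",
      x$spacing, "mm; dose range [", signif(min(x$values), 4), ",",
      signif(max(x$values), 4), "] Gy\n")
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Sum dose grids voxelwise
#'
#' Accumulates per-fraction dose distributions in the common (planning CT)
#' frame. Commutative and associative to floating tolerance.
#'
#' @param doses non-empty list of `dose_grid`s with identical geometry.
#' @return A `dose_grid` holding the voxelwise sum.
#' @export
accumulate <- function(doses) {
  if (!is.list(doses) || length(doses) == 0L) {
    stop("accumulate() needs a non-empty list of dose grids")
  }
  ref <- doses[[1L]]
  total <- ref$values
  for (g in doses[-1L]) {
    if (!same_geometry(ref, g)) stop("dose grids have mismatched geometry")
    total <- total + g$values
  }
  dose_grid(total, ref$spacing, ref$origin)
}

# integer-lattice translation with zero fill: out[i] = x[i - k]
int_shift3 <- function(x, k) {
  d <- dim(x)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    lo_dst <- max(1L, 1L + k[a]); hi_dst <- min(d[a], d[a] + k[a])
    if (lo_dst > hi_dst) return(out)
    dst[[a]] <- lo_dst:hi_dst
    src[[a]] <- (lo_dst - k[a]):(hi_dst - k[a])
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

# translate a dose array by a (possibly fractional) voxel offset via
# trilinear interpolation; out-of-grid regions filled with `background`.
# A uniform translation has identical interpolation weights everywhere, so
# the resample reduces to a weighted sum of eight integer-shifted copies.
shift_array <- function(x, shift_vox, background = 0) {
  k0 <- floor(shift_vox)
  f <- shift_vox - k0
  out <- array(0, dim(x))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) f[1] else 1 - f[1]) *
         (if (cy) f[2] else 1 - f[2]) *
         (if (cz) f[3] else 1 - f[3])
    if (w == 0) next
    out <- out + w * int_shift3(x, as.integer(k0 + c(cx, cy, cz)))
  }
  if (background != 0) {
    # voxels whose full interpolation stencil fell outside the grid
    ones <- array(1, dim(x))
    cov <- shift_array(ones, shift_vox, background = 0)
    out <- out + background * (1 - cov)
  }
  out
}

#' Emulate delivery of one fraction under a rigid setup error
#'
#' The patient is displaced by `shift` (mm) relative to the beams, so the
#' dose in the patient frame is the planned dose resampled at coordinates
#' translated by `-shift` (trilinear interpolation, out-of-grid regions at
#' background 0 Gy), scaled to one fraction (`1/n_fractions` of the course).
#' This rigid "invariant dose" approximation stands in for per-fraction dose
#' recalculation on daily anatomy.
#'
#' @param planned `dose_grid` of the full-course planned dose.
#' @param shift numeric 3-vector, setup error in mm (x, y, z).
#' @param n_fractions number of fractions the course is divided into.
#' @return A `dose_grid` with the single-fraction delivered dose.
#' @export
deliver_fraction <- function(planned, shift, n_fractions) {
  stopifnot(inherits(planned, "dose_grid"), length(shift) == 3L,
            n_fractions >= 1)
  ext <- dim(planned$values) * planned$spacing
  if (any(abs(shift) >= ext)) {
    stop("setup shift exceeds grid extent (", paste(round(ext), collapse = "x"),
         " mm)")
  }
  # out(x) = planned(x - shift): the dose pattern trails the displaced patient
  vox <- as.numeric(shift) / planned$spacing
  dose_grid(shift_array(planned$values, vox) / n_fractions,
            planned$spacing, planned$origin)
}
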