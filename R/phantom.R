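#' Structure mask constructor
#'
#' A boolean field on the patient grid naming one planning structure. Masks
#' live in the planning frame and never move: under setup error the dose
#' moves, the anatomy labels do not.
#'
#' @param name one of `"PTVsc"`, `"PTVcw"`, `"heart"`, `"lung_ipsi"`,
#'   `"breast_contra"` (custom names allowed for external data).
#' @param mask logical 3-D array on the patient grid.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(name, mask) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array")
  if (!any(mask)) stop("structure mask '", name, "' is empty")
  structure(list(name = name, mask = mask), class = "structure_mask")
}

#' Standard structure names of the synthetic cohort
#' @return Character vector of the five structure names.
#' @export
structure_names <- function() {
  c("PTVsc", "PTVcw", "heart", "lung_ipsi", "breast_contra")
}

# separable 1-D convolution of a 3-D array along axis `axis` with kernel k
# (odd length, centred); zero-padded borders
conv_axis <- function(x, k, axis) {
  d <- dim(x)
  r <- (length(k) - 1L) %/% 2L
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  out <- array(0, dp)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    w <- k[j]
    if (w == 0) next
    lo <- max(1L, 1L - off); hi <- min(dp[1], dp[1] - off)
    if (lo > hi) next
    out[lo:hi, , ] <- out[lo:hi, , ] + w * xp[(lo + off):(hi + off), , ]
  }
  aperm(out, order(perm))
}

# Gaussian smoothing with per-axis sd sigma_vox (voxels); separable passes
gauss_smooth3 <- function(x, sigma_vox) {
  if (sigma_vox <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k <- k / sum(k)
  for (a in 1:3) x <- conv_axis(x, k, a)
  x
}

# binary dilation by a Chebyshev ball of radius r_vox (box structuring element)
dilate3 <- function(mask, r_vox) {
  if (r_vox <= 0) return(mask)
  k <- rep(1, 2L * r_vox + 1L)
  x <- mask * 1
  for (a in 1:3) x <- conv_axis(x, k, a)
  x > 1e-9
}

#' Build the phantom anatomy and planned dose
#'
#' Generates a geometric stand-in for a left-sided postmastectomy planning
#' CT: a curved chest-wall target (PTVcw, a left-anterior shell of the torso
#' cylinder), a small supraclavicular box target (PTVsc) superior to it, the
#' heart (ellipsoid, medial and deep to the chest wall), the ipsilateral lung
#' (large ellipsoid beneath the chest wall) and the contralateral breast
#' (right-sided ellipsoid). Structure positions scale with the physical grid
#' extent, so coarser grids keep the same anatomy.
#'
#' The planned dose is `prescription` inside the PTV union expanded by
#' `plan_margin`, falling to 0 Gy background through a sigmoid penumbra of
#' 80--20% width `penumbra_width` (Gaussian-smoothed step); organs at risk
#' receive incidental dose by proximity only.
#'
#' @param config a [cohort_config()].
#' @return A list with elements `planned` (`dose_grid`) and `masks` (named
#'   list of `structure_mask`s).
#' @export
build_phantom <- function(config) {
  validate_cohort_config(config)
  d <- config$grid_shape
  sp <- config$voxel_spacing
  ext <- d * sp
  # voxel-centre coordinates as fractions of extent, per axis
  u <- (seq_len(d[1]) - 0.5) / d[1]
  v <- (seq_len(d[2]) - 0.5) / d[2]
  w <- (seq_len(d[3]) - 0.5) / d[3]
  U <- array(rep(u, times = d[2] * d[3]), d)
  V <- array(rep(rep(v, each = d[1]), times = d[3]), d)
  W <- array(rep(w, each = d[1] * d[2]), d)

  # torso cylinder (axis along z) seen from above; chest wall is the
  # left-anterior part of its shell
  cx <- 0.50; cy <- 0.60; R <- 0.32
  rad <- sqrt((U - cx)^2 + (V - cy)^2)
  ang <- atan2(U - cx, -(V - cy))   # 0 = anterior, +pi/2 = patient left
  ptvcw <- rad >= R - 0.06 & rad <= R &
    ang >= -5 * pi / 180 & ang <= 80 * pi / 180 &
    W >= 0.15 & W <= 0.60
  ptvsc <- U >= 0.53 & U <= 0.73 & V >= 0.25 & V <= 0.45 &
    W >= 0.66 & W <= 0.80
  ell <- function(c0, s) {
    ((U - c0[1]) / s[1])^2 + ((V - c0[2]) / s[2])^2 + ((W - c0[3]) / s[3])^2 <= 1
  }
  heart <- ell(c(0.55, 0.55, 0.35), c(0.10, 0.10, 0.12))
  lung <- ell(c(0.58, 0.55, 0.42), c(0.12, 0.13, 0.22))
  breast <- ell(c(0.26, 0.38, 0.42), c(0.10, 0.10, 0.12))

  masks <- list(
    PTVsc = ptvsc, PTVcw = ptvcw, heart = heart,
    lung_ipsi = lung, breast_contra = breast
  )
  # disjoint targets; anatomy labels may otherwise overlap harmlessly
  masks$PTVcw <- masks$PTVcw & !masks$PTVsc
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!any(m)) stop("phantom structure '", nm, "' is empty on this grid")
    edge <- any(m[c(1, d[1]), , ]) || any(m[, c(1, d[2]), ]) ||
      any(m[, , c(1, d[3])])
    if (edge) stop("phantom structure '", nm, "' truncated by grid boundary")
  }

  ptv <- masks$PTVsc | masks$PTVcw
  plateau <- dilate3(ptv, round(config$plan_margin / sp))
  # 80-20% width of a Gaussian-blurred edge is 2*qnorm(0.8)*sigma = 1.683*sigma
  sigma_mm <- config$penumbra_width / (2 * stats::qnorm(0.8))
  prof <- gauss_smooth3(plateau * 1, sigma_mm / sp)
  prof <- pmin(pmax(prof, 0), 1)
  planned <- dose_grid(config$prescription * prof, sp)

  list(planned = planned,
       masks = Map(structure_mask, names(masks), masks))
}
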