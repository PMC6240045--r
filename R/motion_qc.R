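#' Morphological erosion of a 3-D mask
#'
#' 6-connected erosion (a voxel survives only if all face neighbours are in
#' the mask; out-of-volume counts as background), applied `iterations`
#' times. Zero iterations is the identity.
#'
#' @param mask 3-D logical array.
#' @param iterations Non-negative integer.
#' @return The eroded mask; errors if it becomes empty, naming the
#'   iteration count.
#' @export
erode_mask <- function(mask, iterations = 1) {
  stopifnot(length(dim(mask)) == 3L)
  if (iterations < 0) stop("value error: iterations must be >= 0")
  m <- mask
  for (it in seq_len(iterations)) {
    m <- m & shift3(m, 1, 1) & shift3(m, -1, 1) &
      shift3(m, 1, 2) & shift3(m, -1, 2) &
      shift3(m, 1, 3) & shift3(m, -1, 3)
    if (!any(m)) {
      stop("erode_mask: mask empty after ", it, " iteration(s)")
    }
  }
  m
}

# shift a 3-D array by one voxel along an axis, padding with `fill`
shift3 <- function(a, by, axis, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  n <- d[axis]
  if (by > 0) {
    idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1)
  } else {
    idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# central-difference gradient magnitude (one-sided at volume faces),
# per-axis spacing from voxel_size
gradient_magnitude <- function(vol, voxel_size = c(1, 1, 1)) {
  d <- dim(vol)
  g2 <- array(0, dim = d)
  for (axis in 1:3) {
    fwd <- shift3(vol, -1, axis, fill = NA)
    bwd <- shift3(vol, 1, axis, fill = NA)
    grad <- (fwd - bwd) / (2 * voxel_size[axis])
    one_fwd <- (fwd - vol) / voxel_size[axis]
    one_bwd <- (vol - bwd) / voxel_size[axis]
    grad[is.na(grad) & !is.na(one_fwd)] <- one_fwd[is.na(grad) & !is.na(one_fwd)]
    grad[is.na(grad) & !is.na(one_bwd)] <- one_bwd[is.na(grad) & !is.na(one_bwd)]
    g2 <- g2 + grad^2
  }
  sqrt(g2)
}

#' Motion proxy: gradient SD within the white-matter mask core
#'
#' Motion produces ringing-like artefacts, raising the variance of the
#' intensity gradient; the standard deviation of the gradient magnitude
#' within the eroded white-matter mask therefore serves as a motion proxy.
#' The proxy is invariant to adding a constant to the volume and scales
#' linearly with a multiplicative intensity gain.
#'
#' @param intensities 3-D numeric array.
#' @param wm_mask 3-D logical array, same shape.
#' @param voxel_size Voxel spacing in mm (length 3). Default 1 mm isotropic.
#' @param erosion_iterations Erosions applied to reach the mask core.
#'   Default 2.
#' @return Scalar proxy value.
#' @export
motion_proxy <- function(intensities, wm_mask, voxel_size = c(1, 1, 1),
                         erosion_iterations = 2) {
  stopifnot(identical(dim(intensities), dim(wm_mask)))
  core <- erode_mask(wm_mask, erosion_iterations)
  g <- gradient_magnitude(intensities, voxel_size)
  stats::sd(g[core])
}

#' Compare motion proxies between groups
#'
#' Two-sample Welch t-test of the proxy values between the two groups.
#'
#' @param proxies Numeric vector of per-subject proxy values.
#' @param labels Character/factor vector of group labels (two levels),
#'   same length; each group needs at least 2 subjects.
#' @return List with `t`, `p`, `df` and the underlying `htest`.
#' @export
compare_motion_groups <- function(proxies, labels) {
  stopifnot(length(proxies) == length(labels))
  labels <- as.factor(droplevels(as.factor(labels)))
  if (nlevels(labels) != 2L) stop("compare_motion_groups: need 2 groups")
  if (any(table(labels) < 2L)) {
    stop("compare_motion_groups: each group needs >= 2 subjects")
  }
  lev <- levels(labels)
  ht <- stats::t.test(proxies[labels == lev[1]], proxies[labels == lev[2]])
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), htest = ht)
}
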