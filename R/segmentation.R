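#' Adaptive segmentation parameters
#'
#' Controls the iterative adaptive-threshold delineation: the threshold is
#' updated as `T_{k+1} = alpha * mean(SUV over current region) + beta *
#' background`, started at `t0_fraction` of the local SUV maximum around the
#' seed, until the relative change falls below `tol`.
#'
#' @param alpha fraction of the current region mean entering the threshold,
#'   in (0, 1].
#' @param beta weight of the background term.
#' @param t0_fraction initial threshold as a fraction of the local SUVmax,
#'   in (0, 1).
#' @param tol relative convergence tolerance on the threshold.
#' @param max_iter iteration cap.
#' @param connectivity 6, 18 or 26 neighborhood for the connected component.
#' @param seed_window half-width (voxels) of the cubic window around the
#'   seed searched for the local SUV maximum.
#' @return A validated list of class `segmentation_params`.
#' @export
segmentation_params <- function(alpha = 0.5, beta = 1.0, t0_fraction = 0.4,
                                tol = 0.01, max_iter = 100L,
                                connectivity = 26L, seed_window = 3L) {
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  if (t0_fraction <= 0 || t0_fraction >= 1) stopf("t0_fraction must be in (0, 1)")
  if (tol <= 0) stopf("tol must be > 0")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stopf("max_iter must be >= 1")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) stopf("connectivity must be 6, 18 or 26")
  structure(list(alpha = alpha, beta = beta, t0_fraction = t0_fraction,
                 tol = tol, max_iter = max_iter, connectivity = connectivity,
                 seed_window = as.integer(seed_window)),
            class = "segmentation_params")
}

not_delineable <- function(msg) {
  stop(structure(class = c("petsarc_not_delineable", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Test for the "lesion not delineable" condition
#' @param expr expression to evaluate.
#' @return `TRUE` if `expr` signalled `petsarc_not_delineable`.
#' @export
is_not_delineable <- function(expr) {
  tryCatch({ expr; FALSE },
           petsarc_not_delineable = function(e) TRUE)
}

#' Iterative adaptive-threshold lesion delineation
#'
#' Delineates the volume of interest as the connected component containing
#' the seed above a contrast-adapted threshold. Starting from `T0 =
#' t0_fraction * SUVmax(window around seed)`, the threshold is iterated as
#' `T_{k+1} = alpha * mean(SUV of current region) + beta * background` until
#' `|T_{k+1} - T_k| / T_k < tol` or `max_iter` is reached. The seed is first
#' snapped to the hottest voxel of its local window so that a coarse manual
#' seed suffices.
#'
#' When no uptake above background is present at the seed, or no voxel
#' exceeds the initial threshold, a condition of class
#' `petsarc_not_delineable` is signalled; callers handling follow-up scans
#' may then fall back to [fallback_voi()]. Non-convergence within
#' `max_iter` returns the current mask flagged with `attr(, "converged") =
#' FALSE`.
#'
#' @param vol a [suv_volume()].
#' @param seed_voxel integer length-3 voxel coordinates inside the grid.
#' @param background scalar background SUV (from a reference region).
#' @param params a [segmentation_params()].
#' @return A [lesion_mask()] with attributes `threshold` (converged value),
#'   `iterations`, and `converged` (logical).
#' @export
adaptive_segment <- function(vol, seed_voxel, background,
                             params = segmentation_params()) {
  stopifnot(inherits(vol, "suv_volume"))
  dm <- dim(vol$values)
  seed_voxel <- as.integer(round(seed_voxel))
  if (length(seed_voxel) != 3L || any(seed_voxel < 1L) || any(seed_voxel > dm)) {
    stopf("seed_voxel must lie inside the grid")
  }
  if (background < 0) stopf("background SUV must be >= 0")
  v <- vol$values
  w <- params$seed_window
  win <- lapply(1:3, function(a) {
    max(1L, seed_voxel[a] - w):min(dm[a], seed_voxel[a] + w)
  })
  sub <- v[win[[1]], win[[2]], win[[3]], drop = FALSE]
  local_max <- max(sub)
  if (local_max <= background) {
    not_delineable("no uptake above background at the seed")
  }
  # snap seed to the local maximum voxel
  amax <- which(sub == local_max, arr.ind = TRUE)[1L, ]
  seed_voxel <- c(win[[1]][amax[1]], win[[2]][amax[2]], win[[3]][amax[3]])

  t_k <- params$t0_fraction * local_max
  if (t_k <= background) {
    # contrast too low for an adaptive threshold: T0 would flood background
    not_delineable("initial threshold does not exceed the background level")
  }
  region <- seeded_component(v >= t_k, seed_voxel, params$connectivity)
  if (!any(region)) not_delineable("no voxel above the initial threshold")
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iter) {
    iter <- iter + 1L
    t_next <- params$alpha * mean(v[region]) + params$beta * background
    if (abs(t_next - t_k) / t_k < params$tol) {
      t_k <- t_next
      converged <- TRUE
      break
    }
    t_k <- t_next
    nxt <- seeded_component(v >= t_k, seed_voxel, params$connectivity)
    if (!any(nxt)) break  # threshold rose past the seed: keep last region
    region <- nxt
  }
  out <- lesion_mask(region, vol$spacing)
  attr(out, "threshold") <- t_k
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  out
}

#' Reproduce a baseline VOI on a follow-up scan
#'
#' When the post-therapy lesion is not delineable (uptake has fallen to
#' background), the baseline VOI is reproduced on the follow-up grid by a
#' rigid integer translation supplied by the caller (standing in for
#' anatomical-landmark alignment). The voxel count is preserved exactly.
#'
#' @param baseline_mask a [lesion_mask()] from the baseline study.
#' @param post_vol the follow-up [suv_volume()] (defines the target grid).
#' @param offset integer length-3 voxel translation.
#' @return A [lesion_mask()] on the follow-up grid.
#' @export
fallback_voi <- function(baseline_mask, post_vol, offset = c(0L, 0L, 0L)) {
  stopifnot(inherits(baseline_mask, "lesion_mask"), inherits(post_vol, "suv_volume"))
  check_nonempty(baseline_mask)
  offset <- as.integer(round(offset))
  dm <- dim(post_vol$values)
  ijk <- which(baseline_mask$values, arr.ind = TRUE)
  ijk <- sweep(ijk, 2L, offset, "+")
  if (any(ijk < 1L) || any(sweep(ijk, 2L, dm, ">") > 0)) {
    stopf("translated VOI falls outside the follow-up grid")
  }
  out <- array(FALSE, dm)
  out[ijk] <- TRUE
  lesion_mask(out, post_vol$spacing)
}
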