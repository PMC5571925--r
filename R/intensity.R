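#' Basic SUV statistics inside a VOI
#'
#' `suv_max` is the SUV of the hottest voxel within the mask; `suv_mean` the
#' arithmetic mean over all masked voxels.
#'
#' @param vol a [suv_volume()].
#' @param mask an aligned, nonempty [lesion_mask()].
#' @return Named numeric vector `c(suv_max =, suv_mean =)`.
#' @export
suv_basic <- function(vol, mask) {
  check_aligned(vol, mask)
  check_nonempty(mask)
  x <- vol$values[mask$values]
  c(suv_max = max(x), suv_mean = mean(x))
}

#' Radius (mm) of a 1 cm^3 sphere, the SUVpeak aggregation volume.
#' @export
SUVPEAK_RADIUS_MM <- (3 * 1000 / (4 * pi))^(1 / 3)

#' SUVpeak: hottest 1-cm^3 spherical mean
#'
#' For every candidate center (each masked voxel center), averages the SUV
#' over all grid voxels -- mask-unrestricted -- whose centers lie within the
#' radius of a 1 cm^3 sphere (about 6.204 mm), and returns the maximum such
#' mean. `mode = "fixed_at_max"` restricts the candidate centers to the
#' SUVmax voxel(s), the stricter classical reading; ties are resolved by
#' taking the maximum over all tied voxels, so the result is
#' order-independent.
#'
#' @inheritParams suv_basic
#' @param radius_mm sphere radius; default the 1 cm^3 radius.
#' @param mode `"max_over_centers"` (default) or `"fixed_at_max"`.
#' @return Scalar SUVpeak.
#' @export
suv_peak <- function(vol, mask, radius_mm = SUVPEAK_RADIUS_MM,
                     mode = c("max_over_centers", "fixed_at_max")) {
  mode <- match.arg(mode)
  check_aligned(vol, mask)
  check_nonempty(mask)
  sp <- vol$spacing
  if (any(sp > 2 * radius_mm)) {
    stopf("voxel spacing (%s mm) exceeds the peak-sphere diameter %.3f mm",
          paste(format(sp), collapse = ", "), 2 * radius_mm)
  }
  dm <- dim(vol$values)
  rng <- floor(radius_mm / sp)
  offs <- as.matrix(expand.grid(-rng[1]:rng[1], -rng[2]:rng[2], -rng[3]:rng[3]))
  offs <- offs[rowSums(sweep(offs, 2L, sp, "*")^2) <= radius_mm^2, , drop = FALSE]
  ijk <- which(mask$values, arr.ind = TRUE)
  n <- nrow(ijk)
  sums <- numeric(n)
  cnts <- numeric(n)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(ijk, 2L, offs[r, ], "+")
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dm[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= dm[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= dm[3L]
    if (!any(ok)) next
    lin <- lin_index(nb[ok, , drop = FALSE], dm)
    sums[ok] <- sums[ok] + vol$values[lin]
    cnts[ok] <- cnts[ok] + 1
  }
  means <- sums / cnts
  if (mode == "fixed_at_max") {
    x <- vol$values[mask$values]
    max(means[x == max(x)])
  } else {
    max(means)
  }
}

#' Metabolic tumor volume and total lesion glycolysis
#'
#' MTV is the physical volume of the VOI in mL (`foreground voxels x voxel
#' volume / 1000`); TLG is `SUVmean x MTV`. An empty mask is an error unless
#' `allow_empty = TRUE`, the case of a post-therapy fallback VOI with no
#' residual uptake, which yields `mtv = 0, tlg = 0`.
#'
#' @inheritParams suv_basic
#' @param allow_empty permit an empty mask (returns zeros).
#' @return Named numeric vector `c(mtv =, tlg =)` (mL, mL*SUV).
#' @export
mtv_tlg <- function(vol, mask, allow_empty = FALSE) {
  check_aligned(vol, mask)
  if (!any(mask$values)) {
    if (allow_empty) return(c(mtv = 0, tlg = 0))
    stopf("empty mask")
  }
  mtv <- sum(mask$values) * voxel_volume(mask) / 1000
  c(mtv = mtv, tlg = unname(suv_basic(vol, mask)["suv_mean"]) * mtv)
}

#' Percent change of features between timepoints
#'
#' `delta_f = 100 * (post_f - pre_f) / pre_f` for the intensity/volume
#' metrics. A complete metabolic disappearance (post TLG 0) therefore maps
#' to -100. A zero baseline value leaves that delta undefined (`NA`) with a
#' warning.
#'
#' @param pre,post named numeric feature vectors sharing names.
#' @param features which features to difference.
#' @return Named numeric vector of percent changes, names prefixed `delta_`.
#' @export
delta_percent <- function(pre, post,
                          features = c("suv_max", "suv_peak", "suv_mean",
                                       "tlg", "mtv")) {
  features <- intersect(features, intersect(names(pre), names(post)))
  if (!length(features)) stopf("no common features to difference")
  d <- vapply(features, function(f) {
    if (is.na(pre[[f]]) || is.na(post[[f]])) return(NA_real_)
    if (pre[[f]] == 0) {
      warning(sprintf("baseline %s is 0: delta undefined", f), call. = FALSE)
      return(NA_real_)
    }
    100 * (post[[f]] - pre[[f]]) / pre[[f]]
  }, numeric(1))
  stats::setNames(d, paste0("delta_", features))
}
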