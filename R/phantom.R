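#' Phantom specification
#'
#' Describes a synthetic FDG-avid ellipsoidal lesion on a low-uptake
#' background: grid geometry, lesion placement and contrast, an intra-lesion
#' texture pattern, and Gaussian noise levels. A fixed `seed` makes the
#' generated phantom bit-reproducible.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing numeric length-3 voxel spacing, mm.
#' @param background_suv mean background SUV (g/mL).
#' @param background_noise_sd SD of additive Gaussian noise outside the
#'   lesion, SUV units.
#' @param lesion_center lesion center in voxel coordinates (may be
#'   fractional).
#' @param semi_axes ellipsoid semi-axes, mm, one per grid axis.
#' @param lesion_suv peak lesion SUV; must exceed `background_suv`.
#' @param texture_pattern intra-lesion pattern: `"uniform"`, `"gradient"`,
#'   `list(type = "checkerboard", period = <voxels>)`, or
#'   `list(type = "blobs", count = <n>, amplitude = <SUV>)`.
#' @param noise_sd SD of additive Gaussian noise inside the lesion, SUV.
#' @param seed integer RNG seed.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 40L),
                         spacing = c(2, 2, 2),
                         background_suv = 0.8,
                         background_noise_sd = 0,
                         lesion_center = (grid_shape + 1) / 2,
                         semi_axes = c(15, 12, 12),
                         lesion_suv = 8,
                         texture_pattern = "uniform",
                         noise_sd = 0,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stopf("grid_shape must be 3 positive voxel counts")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stopf("spacing must be positive")
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(semi_axes <= 0)) {
    stopf("semi_axes must be 3 positive lengths in mm")
  }
  if (!is.numeric(lesion_suv) || lesion_suv <= background_suv) {
    stopf("lesion_suv must exceed background_suv (positive lesion contrast required)")
  }
  if (background_suv < 0 || noise_sd < 0 || background_noise_sd < 0) {
    stopf("background_suv and noise SDs must be non-negative")
  }
  if (is.character(texture_pattern)) texture_pattern <- list(type = texture_pattern)
  if (!texture_pattern$type %in% c("uniform", "gradient", "checkerboard", "blobs")) {
    stopf("unknown texture pattern '%s'", texture_pattern$type)
  }
  if (texture_pattern$type == "checkerboard") {
    texture_pattern$period <- as.integer(texture_pattern$period %||% 1L)
    if (texture_pattern$period < 1L) stopf("checkerboard period must be >= 1 voxel")
  }
  if (texture_pattern$type == "blobs") {
    texture_pattern$count <- as.integer(texture_pattern$count %||% 5L)
    texture_pattern$amplitude <- as.numeric(
      texture_pattern$amplitude %||% (0.3 * (lesion_suv - background_suv)))
    if (texture_pattern$count < 1L || texture_pattern$amplitude <= 0) {
      stopf("blobs pattern needs count >= 1 and amplitude > 0")
    }
  }
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 background_suv = background_suv,
                 background_noise_sd = background_noise_sd,
                 lesion_center = as.numeric(lesion_center),
                 semi_axes = semi_axes, lesion_suv = lesion_suv,
                 texture_pattern = texture_pattern, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Ellipsoid membership of voxel centers; errors when the lesion pokes out of
# the grid, naming the overflowing axis.
ellipsoid_mask_array <- function(spec) {
  dm <- spec$grid_shape
  ctr_mm <- (spec$lesion_center - 0.5) * spec$spacing
  extent_mm <- dm * spec$spacing
  for (a in 1:3) {
    if (ctr_mm[a] - spec$semi_axes[a] < 0 || ctr_mm[a] + spec$semi_axes[a] > extent_mm[a]) {
      stopf("lesion extends outside the grid along axis %d", a)
    }
  }
  cx <- ((seq_len(dm[1]) - 0.5) * spec$spacing[1] - ctr_mm[1]) / spec$semi_axes[1]
  cy <- ((seq_len(dm[2]) - 0.5) * spec$spacing[2] - ctr_mm[2]) / spec$semi_axes[2]
  cz <- ((seq_len(dm[3]) - 0.5) * spec$spacing[3] - ctr_mm[3]) / spec$semi_axes[3]
  d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  d2 <= 1
}

# Noise-free lesion pattern values on the foreground voxels (may draw RNG for
# the "blobs" pattern; caller controls the seed).
lesion_pattern_values <- function(spec, inside) {
  ijk <- which(inside, arr.ind = TRUE)
  n <- nrow(ijk)
  tp <- spec$texture_pattern
  if (tp$type == "uniform") return(rep(spec$lesion_suv, n))
  if (tp$type == "gradient") {
    x <- ijk[, 1L]
    rng <- range(x)
    f <- if (diff(rng) == 0) rep(1, n) else (x - rng[1]) / diff(rng)
    return(0.5 * spec$lesion_suv + 0.5 * spec$lesion_suv * f)
  }
  if (tp$type == "checkerboard") {
    par <- (floor((ijk[, 1L] - 1L) / tp$period) +
              floor((ijk[, 2L] - 1L) / tp$period) +
              floor((ijk[, 3L] - 1L) / tp$period)) %% 2L
    lo <- (spec$lesion_suv + spec$background_suv) / 2
    return(ifelse(par == 0L, spec$lesion_suv, lo))
  }
  # blobs: base level plus Gaussian bumps peaking at lesion_suv
  xyz <- sweep(ijk - 0.5, 2L, spec$spacing, "*")
  ctr_mm <- (spec$lesion_center - 0.5) * spec$spacing
  base <- spec$lesion_suv - tp$amplitude
  v <- rep(base, n)
  sd_mm <- min(spec$semi_axes) / 3
  for (b in seq_len(tp$count)) {
    u <- stats::runif(3, -0.6, 0.6)
    bc <- ctr_mm + u * spec$semi_axes
    d2 <- rowSums(sweep(xyz, 2L, bc, "-")^2)
    v <- v + tp$amplitude * exp(-d2 / (2 * sd_mm^2))
  }
  pmin(v, spec$lesion_suv)
}

# Assemble the noise-free image and truth mask, then add clipped noise.
# The texture pattern always draws from spec$seed so that both timepoints of
# a response pair share one heterogeneity pattern; the noise stream has its
# own (per-timepoint) seed.
render_phantom <- function(spec, value_transform = identity,
                           noise_seed = spec$seed + 1L) {
  inside <- ellipsoid_mask_array(spec)
  pat <- with_seed(spec$seed, lesion_pattern_values(spec, inside))
  img <- array(spec$background_suv, spec$grid_shape)
  img[inside] <- value_transform(pat)
  sds <- array(spec$background_noise_sd, spec$grid_shape)
  sds[inside] <- spec$noise_sd
  if (any(sds > 0)) {
    img <- with_seed(noise_seed,
                     img + stats::rnorm(length(img), 0, as.vector(sds)))
  }
  img[img < 0] <- 0
  list(
    volume = suv_volume(img, spec$spacing, "baseline"),
    mask = lesion_mask(inside, spec$spacing)
  )
}

#' Generate a synthetic PET phantom
#'
#' Renders an ellipsoidal FDG-avid lesion (voxel-center membership test)
#' carrying the requested texture pattern on a uniform background, adds
#' Gaussian noise clipped at zero, and returns both the SUV volume and the
#' exact ground-truth lesion mask. Identical seeds give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` ([suv_volume()]), `mask`
#'   ([lesion_mask()]) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' sum(ph$mask$values) * voxel_volume(ph$mask) / 1000  # lesion volume, mL
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  out <- render_phantom(spec)
  out$spec <- spec
  out
}

#' Generate a paired baseline / post-chemotherapy phantom study
#'
#' The post-therapy lesion shrinks isotropically (semi-axes scaled by
#' `volume_scale^(1/3)`, so the enclosed volume scales by `volume_scale`) and
#' its uptake is scaled multiplicatively by `uptake_scale`, floored at the
#' background level: treated tissue returns to background uptake, never
#' below it. `uptake_scale = 0` therefore yields a lesion indistinguishable
#' from background.
#'
#' @param spec a [phantom_spec()] describing the baseline study.
#' @param uptake_scale multiplicative SUV scale for the post lesion, >= 0.
#' @param volume_scale multiplicative volume scale for the post lesion, >= 0.
#' @return A list with `baseline` and `post`, each a `list(volume, mask)`;
#'   masks are the ground-truth ellipsoids of each timepoint.
#' @export
generate_response_pair <- function(spec, uptake_scale, volume_scale = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (uptake_scale < 0 || volume_scale < 0) {
    stopf("uptake_scale and volume_scale must be >= 0")
  }
  baseline <- generate_phantom(spec)
  post_spec <- spec
  post_spec$semi_axes <- spec$semi_axes * volume_scale^(1 / 3)
  post_noise_seed <- spec$seed + 2L
  if (volume_scale == 0) {
    # lesion gone: pure background image, empty truth mask
    post_spec$semi_axes <- spec$spacing * 1e-6
  }
  bg <- spec$background_suv
  post <- render_phantom(post_spec,
                         value_transform = function(v) pmax(bg, uptake_scale * v),
                         noise_seed = post_noise_seed)
  if (volume_scale == 0) {
    post$mask$values[] <- FALSE
    post$volume$values[] <- with_seed(post_noise_seed, {
      img <- array(bg, spec$grid_shape)
      if (spec$background_noise_sd > 0) {
        img <- img + stats::rnorm(length(img), 0, spec$background_noise_sd)
      }
      pmax(img, 0)
    })
  }
  post$volume$timepoint <- "post_cht"
  list(baseline = baseline[c("volume", "mask")], post = post[c("volume", "mask")],
       spec = spec, uptake_scale = uptake_scale, volume_scale = volume_scale)
}

#' Serialize phantom and cohort specifications to YAML
#'
#' @param spec a [phantom_spec()] or [cohort_spec()].
#' @param path output YAML file.
#' @return `path` invisibly; `read_phantom_spec`/`read_cohort_spec` return
#'   the reconstructed spec.
#' @export
write_spec_yaml <- function(spec, path) {
  kind <- if (inherits(spec, "phantom_spec")) "phantom_spec" else if
    (inherits(spec, "cohort_spec")) "cohort_spec" else
      stopf("spec must be a phantom_spec or cohort_spec")
  x <- unclass(spec)
  # named vectors must survive as YAML maps even at length 1
  if (!is.null(x$true_log_hr)) x$true_log_hr <- as.list(x$true_log_hr)
  yaml::write_yaml(c(list(kind = kind), x), path, precision = 15L)
  invisible(path)
}

#' @rdname write_spec_yaml
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  if (!identical(x$kind, "phantom_spec")) stopf("%s is not a phantom_spec", path)
  x$kind <- NULL
  do.call(phantom_spec, x)
}
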