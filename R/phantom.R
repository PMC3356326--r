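#' Dynamic image container
#'
#' A 4D voxel array (x, y, z, frame) in kBq/ml bound to its acquisition
#' schedule and isotropic voxel size.
#'
#' @param data 4D numeric array; 4th dimension indexes frames.
#' @param schedule A [frame_schedule()] with as many frames as `dim(data)[4]`.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, schedule, voxel_size_mm) {
  stopifnot_schedule(schedule)
  if (length(dim(data)) != 4L) stop("`data` must be a 4D array")
  if (dim(data)[4] != n_frames(schedule)) {
    stop("4th dimension must match the number of frames")
  }
  if (voxel_size_mm <= 0) stop("voxel size must be > 0")
  structure(list(data = data, schedule = schedule,
                 voxel_size_mm = voxel_size_mm),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_image> %dx%dx%d voxels x %d frames, %.2f mm voxels\n",
              d[1], d[2], d[3], d[4], x$voxel_size_mm))
  invisible(x)
}

#' Phantom geometry specification
#'
#' Defines a digital phantom as labeled simple geometries (spheres and
#' axis-aligned boxes) on an isotropic voxel grid. Each region carries a
#' [tissue_kinetics()]; a region with `blood = TRUE` (typically the left
#' ventricle) carries the plasma input directly.
#'
#' @param dim_xyz Integer vector of 3 image dimensions.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param regions A named list of regions, each a list with elements
#'   `shape` (`"sphere"` or `"box"`), `center` (voxel indices, 1-based),
#'   `radius` (voxels, spheres) or `half_width` (voxels, boxes),
#'   `kinetics` (a `tissue_kinetics`) and optional `blood` flag.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim_xyz = c(64L, 64L, 64L), voxel_size_mm = 0.8,
                         regions = default_phantom_regions()) {
  dim_xyz <- as.integer(dim_xyz)
  if (length(dim_xyz) != 3L || any(dim_xyz < 1L)) {
    stop("`dim_xyz` must be 3 positive integers")
  }
  if (voxel_size_mm <= 0) stop("voxel size must be > 0")
  if (is.null(names(regions)) || anyDuplicated(names(regions))) {
    stop("regions must have unique names")
  }
  spec <- structure(list(dim_xyz = dim_xyz, voxel_size_mm = voxel_size_mm,
                         regions = regions),
                    class = "phantom_spec")
  # validate geometry now, so errors surface at construction
  masks <- region_masks(spec)
  occupied <- array(0L, dim_xyz)
  for (nm in names(masks)) {
    if (!any(masks[[nm]])) stop("region '", nm, "' is empty or out of bounds")
    occupied <- occupied + masks[[nm]]
  }
  if (any(occupied > 1L)) stop("phantom regions must not overlap")
  spec
}

#' @rdname phantom_spec
#' @details The default layout emulates a tumor-bearing mouse at desk
#'   scale: an integrin-rich tumor (two-tissue kinetics with high
#'   k3/k4), kidney (high-throughput reversible kinetics), liver,
#'   contralateral muscle as reference (one-tissue), and a left-ventricle
#'   blood pool carrying the input function.
#' @export
default_phantom_regions <- function() {
  list(
    tumor = list(shape = "sphere", center = c(18, 32, 32), radius = 6,
                 kinetics = tissue_kinetics(0.25, 0.45, 0.15, 0.04, vB = 0.05)),
    kidney = list(shape = "sphere", center = c(40, 20, 32), radius = 5,
                  kinetics = tissue_kinetics(0.50, 0.25, 0.105, 0.10, vB = 0.05)),
    liver = list(shape = "box", center = c(40, 46, 32), half_width = c(6, 5, 5),
                 kinetics = tissue_kinetics(0.30, 0.30, 0.03, 0.12, vB = 0.05)),
    muscle = list(shape = "sphere", center = c(18, 12, 32), radius = 4,
                  kinetics = tissue_kinetics(0.10, 0.18, 0, 0, vB = 0.02)),
    lv_blood = list(shape = "sphere", center = c(32, 32, 14), radius = 3,
                    kinetics = tissue_kinetics(0, 1), blood = TRUE)
  )
}

region_masks <- function(spec) {
  d <- spec$dim_xyz
  ax <- seq_len(d[1]); ay <- seq_len(d[2]); az <- seq_len(d[3])
  lapply(spec$regions, function(r) {
    ctr <- r$center
    if (identical(r$shape, "sphere")) {
      dx2 <- (ax - ctr[1])^2
      dy2 <- (ay - ctr[2])^2
      dz2 <- (az - ctr[3])^2
      m <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r$radius^2
    } else if (identical(r$shape, "box")) {
      hw <- r$half_width
      m <- outer(outer(abs(ax - ctr[1]) <= hw[1],
                       abs(ay - ctr[2]) <= hw[2], `&`),
                 abs(az - ctr[3]) <= hw[3], `&`)
    } else {
      stop("unknown region shape: ", r$shape)
    }
    m
  })
}

#' Build a dynamic digital phantom with known ground truth
#'
#' Simulates each region's frame-averaged tissue curve from its
#' kinetics (the blood-pool region carries the frame-averaged plasma
#' input), fills the voxel grid, and optionally adds independent
#' per-voxel frame-count noise. Background voxels are zero. Ground-truth
#' V_T and Bp_ND maps are computed from each region's kinetics.
#'
#' @param spec A [phantom_spec()].
#' @param input A `pet_input` plasma model.
#' @param sched A [frame_schedule()].
#' @param noise A [noise_spec()]; `scale = 0` gives a noise-free phantom.
#' @return A list with `image` (a [dynamic_image()]), `truth` (3D arrays
#'   `vt` and `bp`, zero outside regions), `labels` (3D integer array,
#'   0 = background), `region_tacs` (named list of noise-free
#'   [tac()]s), and `spec`.
#' @export
build_phantom <- function(spec, input = feng_input(),
                          sched = schedule_60min_mouse(),
                          noise = noise_spec(scale = 0)) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a `phantom_spec`")
  stopifnot_schedule(sched)
  masks <- region_masks(spec)
  nf <- n_frames(sched)
  d <- spec$dim_xyz
  img <- array(0, c(d, nf))
  vt_map <- array(0, d)
  bp_map <- array(0, d)
  labels <- array(0L, d)
  durs <- frame_durations(sched)

  region_tacs <- list()
  for (i in seq_along(spec$regions)) {
    nm <- names(spec$regions)[i]
    r <- spec$regions[[i]]
    clean <- if (isTRUE(r$blood)) {
      simulate_input_tac(input, sched)
    } else {
      simulate_tac(r$kinetics, input, sched)
    }
    region_tacs[[nm]] <- clean
    idx <- which(masks[[nm]])
    labels[idx] <- i
    if (!isTRUE(r$blood)) {
      vt_map[idx] <- vt_true(r$kinetics)
      bp_map[idx] <- bp_true(r$kinetics)
    }
    nvox <- length(idx)
    vox <- matrix(rep(clean$value, each = nvox), nrow = nvox)
    if (noise$scale > 0) {
      sd <- noise$scale *
        sqrt(pmax(matrix(rep(clean$value, each = nvox), nrow = nvox), 0) /
               matrix(rep(durs, each = nvox), nrow = nvox))
      eps <- withr::with_seed(noise$seed + i, stats::rnorm(nvox * nf, 0, 1))
      vox <- vox + sd * matrix(eps, nrow = nvox)
    }
    for (k in seq_len(nf)) {
      frame <- img[, , , k]
      frame[idx] <- vox[, k]
      img[, , , k] <- frame
    }
  }
  list(image = dynamic_image(img, sched, spec$voxel_size_mm),
       truth = list(vt = vt_map, bp = bp_map),
       labels = labels,
       region_tacs = region_tacs,
       spec = spec)
}
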