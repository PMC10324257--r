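# Synthetic ocular-B-scan-like image generator. Real fundus ultrasound
# shows a dark vitreous cavity bounded by a brighter fundus; vitreous
# opacity (VO) presents as discrete echogenic spots while posterior
# vitreous detachment (PVD) presents as a continuous echogenic membrane.
# The generator emulates exactly that contrast: Gaussian-profile blobs
# for VO, a thickened elliptical arc for PVD, multiplicative speckle on
# top. It makes the two-class learning problem solvable by construction
# so the full pipeline can be exercised without clinical data.

#' Synthetic dataset specification
#'
#' Geometry defaults scale with the image side so the same spec describes
#' both full-size (512, where the default fundus window applies
#' unchanged) and small test images. Lesion intensities must exceed the
#' fundus background level.
#'
#' @param size Square image side in pixels.
#' @param n_per_class Images per class (the emulated regime is 220 + 220).
#' @param noise Multiplicative speckle amplitude; 0 disables noise.
#' @param background Intensity of the elliptical fundus region.
#' @param ellipse List `cx, cy, rx, ry` (pixels); `NULL` = size-relative
#'   default placed inside the default fundus window at size 512.
#' @param vo List: `spot_count` (scalar or range), `spot_radius` range
#'   (pixels), `spot_intensity` range.
#' @param pvd List: `thickness` (pixels), `intensity`, `continuity`
#'   (fraction of the arc rendered), `radius_frac` (arc radius as a
#'   fraction of the ellipse radii).
#' @param seed Base seed for [generate_dataset()].
#' @export
synthetic_spec <- function(size = 512, n_per_class = 220, noise = 0.15,
                           background = 0.18, ellipse = NULL,
                           vo = list(), pvd = list(), seed = 1) {
  osm_check(size >= 16, "size must be >= 16")
  osm_check(n_per_class >= 1, "n_per_class must be >= 1")
  osm_check(noise >= 0, "noise level must be >= 0")
  if (is.null(ellipse)) {
    ellipse <- list(cx = 0.49 * size, cy = 0.34 * size,
                    rx = 0.26 * size, ry = 0.20 * size)
  }
  vo <- modifyList(list(
    spot_count = c(3L, 6L),
    spot_radius = pmax(1, round(size * c(0.010, 0.020))),
    spot_intensity = c(0.75, 0.95)), vo)
  pvd <- modifyList(list(
    thickness = max(2, round(0.008 * size)),
    intensity = 0.85,
    continuity = 1.0,
    radius_frac = 0.75), pvd)
  osm_check(all(vo$spot_radius >= 1), "spot radii must be >= 1 pixel")
  osm_check(all(vo$spot_intensity > background & vo$spot_intensity <= 1) &&
              pvd$intensity > background && pvd$intensity <= 1,
            "lesion intensities must lie in (background, 1]")
  osm_check(pvd$continuity > 0 && pvd$continuity <= 1,
            "continuity must be in (0, 1]")
  structure(list(size = as.integer(size), n_per_class = as.integer(n_per_class),
                 noise = noise, background = background, ellipse = ellipse,
                 vo = vo, pvd = pvd, seed = as.integer(seed)),
            class = "osm_synthetic_spec")
}

# Pixel-center coordinate grids (x rightward, y downward), reused below.
coord_grids <- function(size) {
  list(x = matrix(rep(seq_len(size), each = size), size, size),
       y = matrix(rep(seq_len(size), times = size), size, size))
}

# Add one Gaussian-profile blob in place.
stamp_blob <- function(px, cx, cy, radius, intensity, grids) {
  sg <- max(radius / 1.5, 0.7)
  d2 <- (grids$x - cx)^2 + (grids$y - cy)^2
  pmax(px, intensity * exp(-d2 / (2 * sg^2)))
}

#' Generate one synthetic B-scan-like image
#'
#' @param spec A [synthetic_spec()].
#' @param class `"VO"` (discrete bright spots) or `"PVD"` (continuous
#'   bright arc).
#' @param seed Integer seed; the image is a pure function of
#'   (spec, class, seed).
#' @return A grayscale `osm_image` of side `spec$size`.
#' @export
generate_image <- function(spec, class = c("VO", "PVD"), seed = 1) {
  class <- match.arg(class)
  el <- spec$ellipse
  size <- spec$size
  grids <- coord_grids(size)
  inside <- ((grids$x - el$cx) / el$rx)^2 + ((grids$y - el$cy) / el$ry)^2 <= 1

  rmax <- max(spec$vo$spot_radius)
  if (class == "VO" && 3 * rmax >= min(el$rx, el$ry)) {
    osm_stop("spot radius too large to fit inside the fundus ellipse")
  }
  if (class == "PVD" && spec$pvd$thickness >= min(el$rx, el$ry) / 2) {
    osm_stop("arc thickness too large to fit inside the fundus ellipse")
  }

  px <- matrix(0.03, size, size)
  px[inside] <- spec$background

  with_seed(seed, {
    if (class == "VO") {
      cnt <- spec$vo$spot_count
      n_spots <- if (length(cnt) == 1) as.integer(cnt) else
        sample(seq(cnt[1], cnt[2]), 1)
      # rejection-sample well-separated centres so the blobs stay disjoint
      centres <- matrix(numeric(0), ncol = 3)  # x, y, r
      tries <- 0L
      while (nrow(centres) < n_spots && tries < 5000L) {
        tries <- tries + 1L
        r <- runif(1, spec$vo$spot_radius[1], max(spec$vo$spot_radius))
        th <- runif(1, 0, 2 * pi)
        rho <- sqrt(runif(1)) * 0.78
        cx <- el$cx + rho * el$rx * cos(th)
        cy <- el$cy + rho * el$ry * sin(th)
        if (nrow(centres) > 0) {
          sep <- sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2)
          # blobs stay disjoint above threshold well inside this margin
          if (any(sep < 2.5 * (centres[, 3] + r))) next
        }
        centres <- rbind(centres, c(cx, cy, r))
      }
      if (nrow(centres) < n_spots) {
        osm_stop("could not place the requested spots disjointly inside the ellipse")
      }
      for (i in seq_len(nrow(centres))) {
        inten <- runif(1, spec$vo$spot_intensity[1], spec$vo$spot_intensity[2])
        px <- stamp_blob(px, centres[i, 1], centres[i, 2], centres[i, 3],
                         inten, grids)
      }
    } else {
      # continuous membrane: thickened arc along the posterior (lower)
      # ellipse boundary at radius_frac of the semi-axes
      th0 <- 25 * pi / 180
      th1 <- 155 * pi / 180
      th1 <- th0 + spec$pvd$continuity * (th1 - th0)
      # sample densely enough that consecutive stamps overlap
      n_pts <- max(40L, ceiling(4 * size * (th1 - th0) / (2 * pi)))
      th <- seq(th0, th1, length.out = n_pts)
      fr <- spec$pvd$radius_frac
      axx <- el$cx + fr * el$rx * cos(th)
      ayy <- el$cy + fr * el$ry * sin(th)   # sin > 0 -> below centre
      half <- spec$pvd$thickness / 2
      sg <- max(half, 0.7)
      for (i in seq_len(n_pts)) {
        d2 <- (grids$x - axx[i])^2 + (grids$y - ayy[i])^2
        w <- d2 <= (3 * sg)^2
        px[w] <- pmax(px[w], spec$pvd$intensity * exp(-d2[w] / (2 * sg^2)))
      }
    }
    if (spec$noise > 0) {
      px <- px * (1 + spec$noise * (2 * matrix(runif(size * size), size, size) - 1))
    }
  })
  new_osm_image(array(clamp01(px), dim = c(size, size, 1L)))
}

#' Generate a balanced synthetic dataset on disk
#'
#' Writes `n_per_class` PNG images per class plus a CSV manifest
#' (`manifest.csv`, header `path,label`) and the spec as a YAML config
#' (`spec.yaml`). Per-image seeds are derived deterministically from
#' `spec$seed`, so two runs with the same spec produce identical bytes.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return The manifest (invisibly written to `dir/manifest.csv`).
#' @export
generate_dataset <- function(spec, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    osm_stop(sprintf("output directory '%s' is not writable", dir),
             class = "osm_io_error")
  }
  classes <- c("VO", "PVD")
  paths <- character(0); labels <- character(0)
  for (ci in seq_along(classes)) {
    for (i in seq_len(spec$n_per_class)) {
      img <- generate_image(spec, classes[ci],
                            seed = derive_seed(spec$seed, (ci - 1L) * spec$n_per_class + i))
      p <- file.path(dir, sprintf("%s_%04d.png", classes[ci], i))
      write_image(img, p)
      paths <- c(paths, p); labels <- c(labels, classes[ci])
    }
  }
  m <- manifest(paths, labels)
  write_manifest(m, file.path(dir, "manifest.csv"))
  yaml::write_yaml(unclass(spec), file.path(dir, "spec.yaml"))
  m
}
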