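# Synthetic mammogram phantoms with microcalcification (MC) ground truth.
#
# Real MCs are tiny calcium deposits, 0.1-0.7 mm across, visible as bright
# spots; their spatial distribution carries the diagnostic signal:
# clustered and segmental patterns suggest malignancy, regional and diffuse
# patterns suggest benignity. The generator renders Gaussian-profile bright
# disks on a breast-like low-frequency textured background so the detector
# and classifier can be exercised, and measured, without clinical data.

.archetypes <- c("clustered", "segmental", "regional", "diffuse", "none")
.malignant_archetypes <- c("clustered", "segmental")

#' Specification of a synthetic mammogram phantom
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_spacing_mm physical pixel size (mm per pixel). The default
#'   0.1 mm/px maps the 0.1-0.7 mm MC diameter span onto 1-7 px.
#' @param n_spots number of MCs to render (ignored for archetype "none").
#' @param diameter_range_mm length-2 vector inside `[0.1, 0.7]` mm, the MC
#'   diameter span.
#' @param archetype spatial distribution: "clustered" or "segmental"
#'   (malignant), "regional", "diffuse" or "none" (benign).
#' @param spot_contrast peak spot intensity above background, as a fraction
#'   of the dynamic range, in `(0, 1]`.
#' @param noise_sd standard deviation of additive per-pixel Gaussian noise.
#' @param background_level base background intensity in `[0, 1]`.
#' @param seed integer RNG seed; identical specs give identical phantoms.
#' @param texture_sd amplitude (sd) of the low-frequency parenchymal
#'   texture field added to the background; defaults to `noise_sd`, so a
#'   noise-free spec renders a flat background.
#' @param cluster_radius_mm radius of the disk holding a clustered pattern
#'   (at most 5 mm).
#' @param segment_length_mm,segment_jitter_mm length of and perpendicular
#'   jitter (sd) around the line segment of a segmental pattern. The
#'   jitter stays below one spot diameter: segmental calcifications track
#'   a duct, so the pattern must remain linear rather than a loose band.
#' @param region_size_mm side of the square holding a regional pattern.
#' @param margin_frac fraction of each border kept free of spot centers.
#' @param min_separation_mm minimum center-to-center distance between
#'   spots; the default (largest diameter plus one pixel) keeps individual
#'   MCs resolvable as separate connected components.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(width_px = 320L, height_px = 240L,
                         pixel_spacing_mm = 0.1, n_spots = 12L,
                         diameter_range_mm = c(0.2, 0.5),
                         archetype = c("clustered", "segmental", "regional",
                                       "diffuse", "none"),
                         spot_contrast = 0.4, noise_sd = 0.03,
                         background_level = 0.3, seed = 1L,
                         texture_sd = noise_sd, cluster_radius_mm = 2.5,
                         segment_length_mm = 15, segment_jitter_mm = 0.3,
                         region_size_mm = 20, margin_frac = 0.08,
                         min_separation_mm = diameter_range_mm[2] +
                           pixel_spacing_mm) {
  archetype <- match.arg(archetype)
  stopifnot(width_px >= 1, height_px >= 1, pixel_spacing_mm > 0,
            n_spots >= 0, length(diameter_range_mm) == 2L,
            diameter_range_mm[1] <= diameter_range_mm[2],
            spot_contrast > 0, spot_contrast <= 1, noise_sd >= 0,
            texture_sd >= 0, background_level >= 0, background_level <= 1,
            cluster_radius_mm <= 5)
  if (diameter_range_mm[1] < 0.1 || diameter_range_mm[2] > 0.7)
    stop("diameter_range_mm must lie within [0.1, 0.7] mm (the MC size span)")
  if (archetype != "none" &&
      diameter_range_mm[1] / (2 * pixel_spacing_mm) < 0.5)
    stop("spot radius below 0.5 px at this pixel spacing: ",
         "spots would be sub-resolution")
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         pixel_spacing_mm = pixel_spacing_mm, n_spots = as.integer(n_spots),
         diameter_range_mm = diameter_range_mm, archetype = archetype,
         spot_contrast = spot_contrast, noise_sd = noise_sd,
         background_level = background_level, seed = as.integer(seed),
         texture_sd = texture_sd, cluster_radius_mm = cluster_radius_mm,
         segment_length_mm = segment_length_mm,
         segment_jitter_mm = segment_jitter_mm,
         region_size_mm = region_size_mm, margin_frac = margin_frac,
         min_separation_mm = min_separation_mm),
    class = "phantom_spec")
}

#' Class label implied by a spatial-distribution archetype
#'
#' Clustered and segmental MC distributions are malignant (1); regional,
#' diffuse and spot-free images are benign (0).
#'
#' @param archetype one of "clustered", "segmental", "regional", "diffuse",
#'   "none".
#' @return Integer 0 or 1.
#' @export
archetype_label <- function(archetype) {
  archetype <- match.arg(archetype, .archetypes)
  as.integer(archetype %in% .malignant_archetypes)
}

# Draw spot centers (px, fractional) for an archetype, with rejection
# sampling to keep centers at least min_sep_px apart so individual MCs stay
# countable.
.place_spots <- function(spec) {
  n <- spec$n_spots
  h <- spec$height_px
  w <- spec$width_px
  sp <- spec$pixel_spacing_mm
  mr <- ceiling(spec$margin_frac * h) + 1
  mc <- ceiling(spec$margin_frac * w) + 1
  lo <- c(mr, mc)
  hi <- c(h - mr, w - mc)
  clamp <- function(p) pmin(pmax(p, lo), hi)
  min_sep <- spec$min_separation_mm / sp
  propose <- switch(spec$archetype,
    clustered = {
      r_px <- spec$cluster_radius_mm / sp
      ctr <- c(runif(1, lo[1] + r_px, max(hi[1] - r_px, lo[1] + r_px)),
               runif(1, lo[2] + r_px, max(hi[2] - r_px, lo[2] + r_px)))
      function() {
        rho <- r_px * sqrt(runif(1))
        ang <- runif(1, 0, 2 * pi)
        clamp(ctr + rho * c(sin(ang), cos(ang)))
      }
    },
    segmental = {
      len <- spec$segment_length_mm / sp
      jit <- spec$segment_jitter_mm / sp
      ang <- runif(1, 0, pi)
      u <- c(sin(ang), cos(ang))          # along-segment unit (row, col)
      v <- c(u[2], -u[1])                 # perpendicular
      mid <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
      function() {
        t <- runif(1, -len / 2, len / 2)
        clamp(mid + t * u + rnorm(1, 0, jit) * v)
      }
    },
    regional = {
      side <- spec$region_size_mm / sp
      o <- c(runif(1, lo[1], max(hi[1] - side, lo[1])),
             runif(1, lo[2], max(hi[2] - side, lo[2])))
      function() clamp(o + runif(2, 0, side))
    },
    diffuse = function() c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2])))
  centers <- matrix(0, 0, 2)
  tries <- 0L
  while (nrow(centers) < n && tries < 400L * n) {
    p <- propose()
    tries <- tries + 1L
    if (nrow(centers) == 0L ||
        min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)) >=
          min_sep)
      centers <- rbind(centers, p)
  }
  if (nrow(centers) < n)
    stop("could not place ", n, " spots at least ", round(min_sep, 1),
         " px apart for archetype '", spec$archetype, "'")
  round(centers)
}

# Low-frequency texture: coarse white-noise grid bilinearly upsampled.
.texture_field <- function(h, w, sd) {
  if (sd == 0) return(matrix(0, h, w))
  gh <- max(2L, ceiling(h / 24))
  gw <- max(2L, ceiling(w / 24))
  .resize_plane(matrix(rnorm(gh * gw, 0, sd), gh, gw), h, w)
}

#' Generate a synthetic mammogram phantom
#'
#' Renders `n_spots` bright disks with a radially decaying Gaussian profile
#' (truncated at the nominal radius; the half-peak radius equals the
#' nominal radius, so a half-peak threshold recovers the annotated
#' diameter) on a textured background, then adds per-pixel Gaussian noise
#' and clips to `[0, 1]`. Overlapping spots combine by maximum, so each
#' annotated center remains a local intensity maximum in the noise-free
#' image.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `image` (a [mammogram()] carrying the class label)
#'   and `truth` (list: `spot_centers` integer matrix of (row, col),
#'   `spot_diameters_mm`, `archetype`, `class_label`).
#' @examples
#' ph <- generate_phantom(phantom_spec(archetype = "clustered", seed = 7))
#' ph$truth$class_label  # 1: clustered patterns are malignant
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)
  h <- spec$height_px
  w <- spec$width_px
  bg <- spec$background_level + .texture_field(h, w, spec$texture_sd)
  if (spec$archetype == "none" || spec$n_spots == 0L) {
    centers <- matrix(integer(0), 0, 2)
    diams <- numeric(0)
  } else {
    centers <- .place_spots(spec)
    diams <- runif(spec$n_spots, spec$diameter_range_mm[1],
                   spec$diameter_range_mm[2])
  }
  spots <- matrix(0, h, w)
  for (i in seq_len(nrow(centers))) {
    r_px <- diams[i] / (2 * spec$pixel_spacing_mm)
    sigma <- r_px / sqrt(2 * log(2))     # half-peak at the nominal radius
    ext <- ceiling(r_px)
    rr <- max(1, centers[i, 1] - ext):min(h, centers[i, 1] + ext)
    cc <- max(1, centers[i, 2] - ext):min(w, centers[i, 2] + ext)
    d2 <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, `+`)
    prof <- spec$spot_contrast * exp(-d2 / (2 * sigma^2))
    prof[d2 > r_px^2] <- 0
    spots[rr, cc] <- pmax(spots[rr, cc], prof)
  }
  px <- bg + spots
  if (spec$noise_sd > 0) px <- px + rnorm(h * w, 0, spec$noise_sd)
  px <- pmin(pmax(px, 0), 1)
  label <- archetype_label(spec$archetype)
  list(image = mammogram(px, pixel_spacing_mm = spec$pixel_spacing_mm,
                         label = label),
       truth = list(spot_centers = centers, spot_diameters_mm = diams,
                    archetype = spec$archetype, class_label = label))
}

#' Generate a labeled phantom dataset
#'
#' Produces exactly `n_benign` images with label 0 (cycling through the
#' regional, diffuse and spot-free archetypes) and `n_malignant` with label
#' 1 (cycling through clustered and segmental). Per-image seeds are derived
#' deterministically from `seed`, so the whole collection is reproducible
#' bit for bit.
#'
#' @param n_benign,n_malignant non-negative image counts.
#' @param base_spec a [phantom_spec()] providing geometry, contrast and
#'   noise settings; its archetype and seed are overridden per image.
#' @param seed integer master seed.
#' @return A list with `phantoms` (list of [generate_phantom()] results)
#'   and `manifest` (data.frame: index, label, archetype, n_spots, seed).
#' @export
generate_dataset <- function(n_benign, n_malignant,
                             base_spec = phantom_spec(), seed = 42L) {
  stopifnot(n_benign >= 0, n_malignant >= 0)
  benign_arch <- c("regional", "diffuse", "none")
  malignant_arch <- c("clustered", "segmental")
  archs <- c(rep_len(benign_arch, n_benign),
             rep_len(malignant_arch, n_malignant))
  n <- n_benign + n_malignant
  phantoms <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- base_spec
    sp$archetype <- archs[i]
    sp$seed <- as.integer((as.numeric(seed) * 48271 + i * 9973) %%
                            2147483647)
    ph <- generate_phantom(sp)
    phantoms[[i]] <- ph
    rows[[i]] <- data.frame(index = i, label = ph$truth$class_label,
                            archetype = archs[i],
                            n_spots = nrow(ph$truth$spot_centers),
                            seed = sp$seed)
  }
  manifest <- if (n > 0L) do.call(rbind, rows)
              else data.frame(index = integer(0), label = integer(0),
                              archetype = character(0), n_spots = integer(0),
                              seed = integer(0))
  list(phantoms = phantoms, manifest = manifest)
}

#' Write a phantom dataset to disk
#'
#' Writes one PNG per phantom plus `manifest.csv` (filename, label,
#' archetype, n_spots, seed) and a per-image `*_truth.csv` of spot centers
#' and diameters.
#'
#' @param dataset result of [generate_dataset()].
#' @param out_dir output directory, created if needed.
#' @return The manifest data.frame (with a `filename` column), invisibly.
#' @export
write_phantom_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  man$filename <- sprintf("phantom_%04d.png", man$index)
  for (i in seq_len(nrow(man))) {
    ph <- dataset$phantoms[[i]]
    write_mammogram_png(ph$image, file.path(out_dir, man$filename[i]))
    truth <- ph$truth
    write.csv(data.frame(row = truth$spot_centers[, 1],
                         col = truth$spot_centers[, 2],
                         diameter_mm = truth$spot_diameters_mm),
              file.path(out_dir, sub("\\.png$", "_truth.csv",
                                     man$filename[i])),
              row.names = FALSE)
  }
  write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
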