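# Speckle phantom generator: hypoechoic star-convex lesions with irregular
# margins on a smoothly varying echogenic background, multiplicative
# gamma-distributed speckle, and optional posterior acoustic shadowing.
# Fully deterministic given (spec, seed, index).

#' Phantom generation settings
#'
#' @param image_size pixels per side (square, >= 32).
#' @param lesion_count number of non-overlapping lesions (>= 0).
#' @param lesion_area_fraction_range min/max of the per-lesion mask-area
#'   fraction, both in (0, 1).
#' @param boundary_irregularity amplitude of the radial contour perturbation
#'   (0 = smooth ellipse).
#' @param lesion_contrast multiplicative intensity factor of the hypoechoic
#'   interior, in (0, 1) (smaller = darker lesion).
#' @param speckle_scale shape of the multiplicative unit-mean gamma speckle
#'   (larger = smoother).
#' @param shadow_probability probability of a posterior shadow band under
#'   each lesion.
#' @param seed base RNG seed; (spec, seed, index) determines every pixel.
#' @return validated list of class "phantom_spec".
#' @export
phantom_spec <- function(image_size = 256L, lesion_count = 1L,
                         lesion_area_fraction_range = c(0.05, 0.15),
                         boundary_irregularity = 0.15,
                         lesion_contrast = 0.45, speckle_scale = 6,
                         shadow_probability = 0.3, seed = 1L) {
  r <- lesion_area_fraction_range
  if (image_size < 32L) stop("image_size must be >= 32")
  if (length(r) != 2L || r[1] >= r[2] || r[1] <= 0 || r[2] >= 1) {
    stop("lesion_area_fraction_range must be an increasing pair in (0,1)")
  }
  if (lesion_count < 0L) stop("lesion_count must be >= 0")
  if (lesion_contrast <= 0 || lesion_contrast >= 1) {
    stop("lesion_contrast must be in (0,1)")
  }
  if (speckle_scale <= 0) stop("speckle_scale must be positive")
  if (shadow_probability < 0 || shadow_probability > 1) {
    stop("shadow_probability must be in [0,1]")
  }
  if (boundary_irregularity < 0) stop("boundary_irregularity must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 lesion_count = as.integer(lesion_count),
                 lesion_area_fraction_range = as.numeric(r),
                 boundary_irregularity = boundary_irregularity,
                 lesion_contrast = lesion_contrast,
                 speckle_scale = speckle_scale,
                 shadow_probability = shadow_probability,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth periodic radial perturbation from a low-order random Fourier series,
# normalized to unit RMS
radial_perturbation <- function() {
  amps <- rnorm(4)
  phases <- runif(4, 0, 2 * pi)
  f <- function(theta) {
    s <- 0
    for (m in 1:4) s <- s + amps[m] * cos((m + 1) * theta + phases[m])
    s
  }
  rms <- sqrt(mean(f(seq(0, 2 * pi, length.out = 720))^2))
  if (rms < 1e-9) return(function(theta) theta * 0)
  function(theta) f(theta) / rms
}

# rasterize one lesion; returns logical mask or NULL if out of canvas
lesion_mask <- function(S, center, r0, aspect, orient, irr, pert) {
  rmax <- r0 * max(aspect, 1 / aspect) * (1 + 2.5 * irr)
  lo <- pmax(1, floor(center - rmax)); hi <- pmin(S, ceiling(center + rmax))
  if (any(center - rmax < 1) || any(center + rmax > S)) return(NULL)
  ys <- lo[1]:hi[1]; xs <- lo[2]:hi[2]
  dy <- outer(ys - center[1], rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - center[2])
  co <- cos(orient); si <- sin(orient)
  u <- (co * dx + si * dy) / aspect
  v <- (-si * dx + co * dy) * aspect
  r <- sqrt(u^2 + v^2)
  ang <- atan2(v, u)
  inside <- r <= r0 * (1 + irr * pert(ang))
  m <- matrix(FALSE, S, S)
  m[ys, xs] <- inside
  m
}

#' Generate one phantom image with its ground-truth mask
#'
#' Background echogenicity varies smoothly; each lesion is a star-convex
#' region (ellipse with a low-order Fourier radial perturbation) whose
#' interior is darkened multiplicatively; with some probability a soft
#' posterior shadow band is drawn under a lesion; the whole field is
#' multiplied by unit-mean gamma speckle and min-max normalized to [0, 1].
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param index sample index (>= 1); part of the RNG stream so each index is
#'   an independent, reproducible draw.
#' @return list of class "image_sample": \code{image} (matrix in [0,1]),
#'   \code{mask} (0/1 matrix), \code{id}, \code{fold} (NA here).
#' @export
generate_phantom <- function(spec, index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed((spec$seed %% 1000003L) * 2011L + index)
  S <- spec$image_size
  irr <- spec$boundary_irregularity
  # smooth background echogenicity in ~[0.6, 0.9]
  coarse <- matrix(runif(64, -1, 1), 8, 8)
  bg <- 0.75 + 0.12 * resize_bilinear(coarse, S, S)
  clean <- bg
  mask <- matrix(FALSE, S, S)
  rng <- spec$lesion_area_fraction_range
  if (spec$lesion_count > 0L) {
    for (j in seq_len(spec$lesion_count)) {
      placed <- FALSE
      for (try in 1:200) {
        frac <- runif(1, rng[1], rng[2])
        r0 <- S * sqrt(frac / pi) / sqrt(1 + irr^2)
        aspect <- runif(1, 0.75, 1.3)
        orient <- runif(1, 0, pi)
        center <- runif(2, 1, S)
        pert <- radial_perturbation()
        lm <- lesion_mask(S, center, r0, aspect, orient, irr, pert)
        if (is.null(lm) || !any(lm) || any(lm & mask)) next
        mask <- mask | lm
        clean[lm] <- clean[lm] * spec$lesion_contrast
        if (runif(1) < spec$shadow_probability) {
          cols <- range(which(colSums(lm) > 0))
          bottom <- max(which(rowSums(lm) > 0))
          if (bottom < S) {
            depth <- (bottom + 1):S
            fade <- 0.55 + 0.35 * exp(-(depth - bottom) / (0.4 * S))
            sub <- clean[depth, cols[1]:cols[2], drop = FALSE]
            clean[depth, cols[1]:cols[2]] <- sweep(sub, 1L, fade, "*")
          }
        }
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place lesion ", j,
             " after 200 attempts; image too small for the requested area")
      }
    }
  }
  k <- spec$speckle_scale
  speckle <- matrix(rgamma(S * S, shape = k, rate = k), S, S)
  img <- clean * speckle
  rngv <- range(img)
  img <- if (rngv[2] > rngv[1]) (img - rngv[1]) / (rngv[2] - rngv[1]) else img * 0
  structure(list(image = img, mask = mask + 0,
                 id = sprintf("phantom_%05d", index), fold = NA_integer_),
            class = "image_sample")
}

#' Generate a phantom dataset on disk with a cross-validation manifest
#'
#' Writes \code{images/<id>.png} and \code{masks/<id>.png} (8-bit grayscale,
#' masks 0/255) plus \code{manifest.csv} with columns
#' \code{id,image_path,mask_path,fold}. Folds are assigned round-robin so
#' sizes differ by at most one and are image-disjoint.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param n number of samples (>= k_folds).
#' @param k_folds number of folds (>= 2).
#' @param out_dir output directory (created if needed).
#' @return the manifest data.frame (paths relative to \code{out_dir}).
#' @export
generate_dataset <- function(spec, n, k_folds = 5L, out_dir) {
  stopifnot(n >= k_folds, k_folds >= 2L)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_phantom(spec, i)
    ip <- file.path("images", paste0(s$id, ".png"))
    mp <- file.path("masks", paste0(s$id, ".png"))
    png::writePNG(s$image, file.path(out_dir, ip))
    png::writePNG(s$mask, file.path(out_dir, mp))
    rows[[i]] <- data.frame(id = s$id, image_path = ip, mask_path = mp,
                            fold = ((i - 1L) %% k_folds) + 1L,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Generate phantoms in memory with fold assignments
#'
#' Convenience used by the training harness and tests: returns the samples
#' (named by id) and a manifest data.frame without touching disk.
#' @param spec a \code{\link{phantom_spec}}.
#' @param n,k_folds as in \code{\link{generate_dataset}}.
#' @export
generate_samples <- function(spec, n, k_folds = 5L) {
  samples <- lapply(seq_len(n), function(i) generate_phantom(spec, i))
  ids <- vapply(samples, `[[`, character(1), "id")
  names(samples) <- ids
  manifest <- data.frame(id = ids, image_path = NA_character_,
                         mask_path = NA_character_,
                         fold = ((seq_len(n) - 1L) %% k_folds) + 1L,
                         stringsAsFactors = FALSE)
  list(samples = samples, manifest = manifest)
}
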