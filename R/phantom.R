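# Synthetic beating-heart phantom: a contracting myocardial annulus with
# optional lesions that alter both local intensity and local motion, plus
# the degradation and augmentation operators used to stress the pipeline.

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a cine sequence
#'
#' A cine sequence is an ordered stack of 2-D frames covering one cardiac
#' cycle, stored as a `T x H x W` array with intensities in `[0, 1]` and a
#' strictly increasing cardiac phase in `[0, 1)` per frame.
#'
#' @param frames `T x H x W` numeric array, finite, in `[0, 1]`.
#' @param frame_phase Numeric vector of length `T`, strictly increasing,
#'   in `[0, 1)`. Defaults to a uniform sampling of the cycle.
#' @param pixel_spacing In-plane pixel spacing in mm (metadata only).
#' @return An object of class `cine_sequence`.
#' @export
cine_sequence <- function(frames, frame_phase = NULL, pixel_spacing = 1.5) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  T <- dim(frames)[1]
  if (T < 2) stop("a cine sequence needs at least 2 frames")
  if (!all(is.finite(frames))) stop("frame intensities must be finite")
  if (min(frames) < -1e-9 || max(frames) > 1 + 1e-9)
    stop("frame intensities must lie in [0, 1]")
  if (is.null(frame_phase)) frame_phase <- (seq_len(T) - 1) / T
  if (length(frame_phase) != T || any(diff(frame_phase) <= 0) ||
      any(frame_phase < 0) || any(frame_phase >= 1))
    stop("frame_phase must be strictly increasing within [0, 1)")
  structure(list(frames = frames, frame_phase = frame_phase,
                 pixel_spacing = pixel_spacing),
            class = "cine_sequence")
}

#' @export
print.cine_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("cine_sequence: %d frames of %d x %d, intensity [%.3f, %.3f]\n",
              d[1], d[2], d[3], min(x$frames), max(x$frames)))
  invisible(x)
}

#' Phantom configuration
#'
#' Parameters of the synthetic beating-heart phantom. The myocardium is an
#' annulus whose radius contracts sinusoidally over one cardiac cycle
#' (period = `n_frames`). Lesions are discs attached to the myocardium that
#' shift local intensity by `intensity_delta` and scale local displacement
#' by `1 - motion_damping`, so both appearance and motion carry lesion
#' signal. Positive `intensity_delta` mimics bright (infarct-like) tissue,
#' negative values dark (edema-like) tissue on the cine contrast.
#'
#' @param height,width Image size in pixels. Defaults 224 x 224.
#' @param n_frames Frames per cardiac cycle (>= 2), default 20.
#' @param ring_center `(row, col)` centre of the annulus, default the image
#'   centre.
#' @param ring_radii `(inner, outer)` radii of the annulus in pixels at
#'   end-diastole; default `(0.18, 0.32) * min(height, width)`.
#' @param contraction_amplitude Peak radial contraction as a fraction of
#'   the outer radius, default 0.15.
#' @param lesion_specs List of lesions; each a list with fields `center`
#'   (`(row, col)` pixels), `radius` (pixels), `intensity_delta` (in
#'   `[-1, 1]`) and `motion_damping` (in `[0, 1]`; 1 = akinetic).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise,
#'   default 0.01.
#' @param seed Integer seed controlling the noise realisation.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(height = 224L, width = 224L, n_frames = 20L,
                           ring_center = NULL, ring_radii = NULL,
                           contraction_amplitude = 0.15,
                           lesion_specs = list(), noise_sd = 0.01,
                           seed = 1L) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (height < 8 || width < 8) stop("image too small")
  if (is.null(ring_center)) ring_center <- c((height + 1) / 2, (width + 1) / 2)
  if (is.null(ring_radii))
    ring_radii <- c(0.18, 0.32) * min(height, width)
  if (ring_radii[1] >= ring_radii[2])
    stop("inner ring radius must be smaller than outer radius")
  if (contraction_amplitude < 0 || contraction_amplitude >= 1)
    stop("contraction_amplitude must be in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  for (les in lesion_specs) {
    stopifnot(is.list(les), length(les$center) == 2, les$radius > 0)
    if (les$intensity_delta < -1 || les$intensity_delta > 1)
      stop("lesion intensity_delta must be in [-1, 1]")
    if (les$motion_damping < 0 || les$motion_damping > 1)
      stop("lesion motion_damping must be in [0, 1]")
    if (les$center[1] - les$radius < 1 || les$center[1] + les$radius > height ||
        les$center[2] - les$radius < 1 || les$center[2] + les$radius > width)
      stop("lesion lies (partly) outside the image")
    d <- sqrt(sum((les$center - ring_center)^2))
    if (d + les$radius < ring_radii[1] || d - les$radius > ring_radii[2])
      stop("lesion circle does not intersect the myocardial annulus")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_frames = as.integer(n_frames), ring_center = ring_center,
                 ring_radii = ring_radii,
                 contraction_amplitude = contraction_amplitude,
                 lesion_specs = lesion_specs, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Default mid-wall lesion specification for a phantom grid
#'
#' Places a single lesion on the mid-wall of the default annulus at 45
#' degrees, with radius `0.09 * min(height, width)`.
#'
#' @param height,width Phantom grid size.
#' @param intensity_delta,motion_damping Lesion contrast and motion damping.
#' @return A one-element `lesion_specs` list.
#' @export
default_lesion <- function(height, width, intensity_delta = 0.2,
                           motion_damping = 0.8) {
  ctr <- c((height + 1) / 2, (width + 1) / 2)
  rmid <- mean(c(0.18, 0.32)) * min(height, width)
  ang <- -pi / 4
  list(list(center = c(ctr[1] + rmid * sin(ang), ctr[2] + rmid * cos(ang)),
            radius = 0.09 * min(height, width),
            intensity_delta = intensity_delta,
            motion_damping = motion_damping))
}

# Contraction scale c(t) for 0-based frame index t: 1 at end-diastole,
# 1 - amplitude at peak systole, sinusoidal with period n_frames.
#' @noRd
.contraction_scale <- function(t, n_frames, amplitude) {
  1 - amplitude * (1 - cos(2 * pi * t / n_frames)) / 2
}

# Fixed harmonic mixture emulating trabecular/speckle-like myocardial
# texture in material coordinates (angular wavenumbers are integers so the
# pattern is periodic in theta). Gradients are present in both the radial
# and tangential directions nearly everywhere, which real cine texture
# provides and dense optical flow relies on.
.texture_table <- list(
  k_theta = c(2L, 7L, 4L, 9L, 3L, 6L, 8L, 5L, 2L, 7L, 4L, 6L),
  k_r     = c(0.09, 0.13, 0.17, 0.08, 0.15, 0.11, 0.19, 0.10,
              0.14, 0.18, 0.12, 0.16),             # cycles / px (5-12 px)
  phase   = c(0.4, 2.9, 1.3, 5.1, 3.7, 0.9, 4.4, 2.2, 5.8, 1.7, 3.1, 0.2),
  amp     = c(0.9, 0.7, 1.0, 0.6, 0.8, 0.9, 0.5, 1.0, 0.7, 0.8, 0.6, 0.9))

#' @noRd
.ring_texture <- function(rm, theta, radii) {
  tt <- .texture_table
  acc <- 0
  for (i in seq_along(tt$amp))
    acc <- acc + tt$amp[i] *
      sin(tt$k_theta[i] * theta + 2 * pi * tt$k_r[i] * rm + tt$phase[i])
  0.12 * acc / sqrt(sum(tt$amp^2) / 2)   # approx unit-sd mixture, sd 0.12
}

# Healthy phantom intensity as a function of material radius and angle.
#' @noRd
.phantom_intensity <- function(rm, theta, radii) {
  w_edge <- 1.2
  inner <- .smoothstep(radii[1] - rm, w_edge)
  ringm <- .smoothstep(rm - radii[1], w_edge) * .smoothstep(radii[2] - rm, w_edge)
  tex <- .ring_texture(rm, theta, radii)
  0.15 + 0.60 * inner + (0.40 + tex) * ringm
}

#' Generate a synthetic cine sequence with ground truth
#'
#' Renders one cardiac cycle of a contracting annular myocardium. Frames
#' are generated analytically in material coordinates so that the returned
#' `true_flow` is the exact displacement field of the rendered motion:
#' `warp(frames[t], true_flow[t])` reproduces `frames[t + 1]` up to
#' interpolation error. Lesions displace with a damped version of the
#' contraction and shift intensity, giving both appearance and motion
#' signal to downstream clustering.
#'
#' @param config A [phantom_config()].
#' @return A list with components `sequence` (a [cine_sequence()]) and
#'   `truth`, where `truth` holds `myocardium_mask` and `lesion_mask`
#'   (`T x H x W` logical), `true_flow` (a [flow_field()] of exact
#'   per-frame-pair displacements), `pathology_map` (`H x W` in `[0, 1]`,
#'   the blurred time-maximum lesion support) and `class_label` (one of
#'   `"normal"`, `"infarct"`, `"edema"`, `"mixed"`).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$height; w <- config$width; T <- config$n_frames
  ctr <- config$ring_center; radii <- config$ring_radii
  A <- config$contraction_amplitude
  lesions <- config$lesion_specs
  w_edge <- 1.2

  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dr <- rows - ctr[1]; dc <- cols - ctr[2]
  rho <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)

  cs <- .contraction_scale(0:(T - 1), T, A)
  # per-lesion damped scales g_l(t) and material centres
  gs <- lapply(lesions, function(les)
    1 + (cs - 1) * (1 - les$motion_damping))

  lesion_alpha <- function(t_idx) {
    # soft support of each lesion at frame t (1-based index), H x W each
    lapply(seq_along(lesions), function(li) {
      g <- gs[[li]][t_idx]
      mr <- ctr[1] + dr / g; mc <- ctr[2] + dc / g
      d <- sqrt((mr - lesions[[li]]$center[1])^2 +
                (mc - lesions[[li]]$center[2])^2)
      .smoothstep(lesions[[li]]$radius - d, w_edge)
    })
  }

  frames <- array(0, c(T, h, w))
  myo <- array(FALSE, c(T, h, w))
  les_mask <- array(FALSE, c(T, h, w))
  alphas <- vector("list", T)

  for (t in seq_len(T)) {
    cc <- cs[t]
    rm_c <- rho / cc
    img <- .phantom_intensity(rm_c, theta, radii)
    al <- lesion_alpha(t)
    alphas[[t]] <- al
    any_alpha <- matrix(0, h, w)
    for (li in seq_along(lesions)) {
      g <- gs[[li]][t]
      rm_g <- rho / g
      img_l <- .phantom_intensity(rm_g, theta, radii) +
        lesions[[li]]$intensity_delta
      a <- al[[li]]
      img <- (1 - a) * img + a * img_l
      any_alpha <- pmax(any_alpha, a)
    }
    ring_hard <- rm_c >= radii[1] & rm_c <= radii[2]
    les_hard <- any_alpha >= 0.5
    myo[t, , ] <- ring_hard | les_hard
    les_mask[t, , ] <- les_hard
    frames[t, , ] <- .clamp(img, 0, 1)
  }

  if (config$noise_sd > 0) {
    frames <- .with_seed(config$seed, {
      frames + array(stats::rnorm(length(frames), sd = config$noise_sd),
                     dim(frames))
    })
    frames <- .clamp(frames, 0, 1)
  }

  # exact displacement field per consecutive pair, in the backward-warp
  # convention: frames[t + 1](x) = frames[t](x + v_t(x))
  flow <- array(0, c(T - 1, h, w, 2))
  for (t in seq_len(T - 1)) {
    s_c <- cs[t] / cs[t + 1] - 1
    vr <- s_c * dr; vc <- s_c * dc
    al_next <- alphas[[t + 1]]
    for (li in seq_along(lesions)) {
      s_g <- gs[[li]][t] / gs[[li]][t + 1] - 1
      a <- al_next[[li]]
      vr <- (1 - a) * vr + a * (s_g * dr)
      vc <- (1 - a) * vc + a * (s_g * dc)
    }
    flow[t, , , 1] <- vr
    flow[t, , , 2] <- vc
  }

  patho <- matrix(0, h, w)
  if (length(lesions) > 0) {
    sup <- matrix(0, h, w)
    for (t in seq_len(T)) sup <- pmax(sup, Reduce(pmax, alphas[[t]]))
    patho <- .gaussian_smooth(sup, 2)
    if (max(patho) > 0) patho <- patho / max(patho)
  }

  deltas <- vapply(lesions, function(l) l$intensity_delta, numeric(1))
  class_label <- if (length(deltas) == 0) "normal"
    else if (all(deltas > 0)) "infarct"
    else if (all(deltas < 0)) "edema"
    else "mixed"

  list(sequence = cine_sequence(frames),
       truth = list(myocardium_mask = myo, lesion_mask = les_mask,
                    true_flow = flow_field(flow),
                    pathology_map = patho, class_label = class_label))
}

#' Degrade a cine sequence by bicubic down/upsampling plus noise
#'
#' Emulates acquisition at a coarser grid: each frame is bicubically
#' downsampled by `factor`, bicubically upsampled back to the original
#' grid, and corrupted with additive Gaussian noise clipped to `[0, 1]`.
#'
#' @param seq A [cine_sequence()].
#' @param factor Integer >= 1 dividing both height and width.
#' @param noise_sd Noise standard deviation (intensity units).
#' @param seed Optional integer seed for the noise realisation.
#' @return A degraded [cine_sequence()]; the attribute `"work_dim"` records
#'   the intermediate grid size.
#' @export
degrade <- function(seq, factor = 2L, noise_sd = 0.02, seed = NULL) {
  stopifnot(inherits(seq, "cine_sequence"))
  d <- dim(seq$frames); T <- d[1]; h <- d[2]; w <- d[3]
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (h %% factor != 0 || w %% factor != 0)
    stop(sprintf("factor %d does not divide the %d x %d grid", factor, h, w))
  h2 <- h %/% factor; w2 <- w %/% factor
  out <- array(0, d)
  for (t in seq_len(T)) {
    f <- seq$frames[t, , ]
    if (factor > 1) f <- .bicubic_resize(.bicubic_resize(f, h2, w2), h, w)
    out[t, , ] <- f
  }
  if (noise_sd > 0)
    out <- .with_seed(seed, out + array(stats::rnorm(length(out), sd = noise_sd),
                                        dim(out)))
  out <- .clamp(out, 0, 1)
  res <- cine_sequence(out, seq$frame_phase, seq$pixel_spacing)
  attr(res, "work_dim") <- c(h2, w2)
  res
}

#' Augment an image (and mask) with rotation, elastic deformation and
#' intensity shift
#'
#' Applies, in one resampling pass: a rotation drawn uniformly in
#' `[-max_rotation, max_rotation]` degrees about the image centre, a smooth
#' random elastic displacement field with per-pixel standard deviation
#' `elastic_sd` pixels, and a global multiplicative intensity factor drawn
#' in `1 +/- max_intensity_shift`. The identical geometric transform is
#' applied to the mask (nearest-neighbour).
#'
#' @param image `H x W` numeric matrix.
#' @param mask Optional `H x W` binary matrix transformed alongside.
#' @param max_rotation Maximum absolute rotation, degrees (default 20).
#' @param elastic_sd Per-pixel displacement standard deviation, pixels
#'   (default 5).
#' @param max_intensity_shift Maximum relative intensity change (default
#'   0.1, i.e. 10 percent).
#' @param seed Optional integer seed.
#' @return `list(image =, mask =)` with the transformed arrays.
#' @export
augment <- function(image, mask = NULL, max_rotation = 20, elastic_sd = 5,
                    max_intensity_shift = 0.1, seed = NULL) {
  stopifnot(is.matrix(image), max_rotation >= 0, elastic_sd >= 0,
            max_intensity_shift >= 0, max_intensity_shift < 1)
  if (!is.null(mask) && !all(dim(mask) == dim(image)))
    stop("mask shape does not match image shape")
  h <- nrow(image); w <- ncol(image)
  .with_seed(seed, {
    theta <- if (max_rotation > 0)
      stats::runif(1, -max_rotation, max_rotation) * pi / 180 else 0
    gain <- if (max_intensity_shift > 0)
      1 + stats::runif(1, -max_intensity_shift, max_intensity_shift) else 1
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    # inverse rotation: sample source at R(-theta) (x - c) + c
    sr <- cy + cos(theta) * (rows - cy) - sin(theta) * (cols - cx)
    sc <- cx + sin(theta) * (rows - cy) + cos(theta) * (cols - cx)
    if (elastic_sd > 0) {
      sm <- max(4, min(h, w) / 16)
      mk <- function() {
        f <- .gaussian_smooth(matrix(stats::rnorm(h * w), h, w), sm)
        f / max(stats::sd(f), 1e-12)
      }
      sr <- sr + elastic_sd * mk()
      sc <- sc + elastic_sd * mk()
    }
    out <- matrix(.bilinear_sample(image, as.vector(sr), as.vector(sc)), h, w)
    out <- out * gain
    mout <- if (is.null(mask)) NULL else
      matrix(.nearest_sample(mask, as.vector(sr), as.vector(sc)), h, w)
    list(image = out, mask = mout)
  })
}
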