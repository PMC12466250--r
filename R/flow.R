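# Dense optical flow between consecutive cine frames: a deterministic
# coarse-to-fine Horn-Schunck solver, plus backward warping of frames and
# masks. Flow vectors are (drow, dcol) in pixels per frame and follow the
# backward-warp convention
#     frame[t + 1](x)  ~=  frame[t](x + v_t(x)),
# i.e. v_t points from a pixel at time t + 1 to its source at time t, so
# that warp(frame[t], v_t) aligns frame t onto frame t + 1.

#' Construct a flow field
#'
#' @param vectors `(T - 1) x H x W x 2` numeric array of `(drow, dcol)`
#'   displacements in pixels per frame.
#' @param valid_mask Optional logical vector of length `T - 1`; frame pairs
#'   flagged `FALSE` (e.g. by [phase_normalize()]) are skipped by
#'   consumers such as [motion_integral()].
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(vectors, valid_mask = NULL) {
  stopifnot(is.array(vectors), length(dim(vectors)) == 4,
            dim(vectors)[4] == 2)
  if (!all(is.finite(vectors))) stop("flow vectors must be finite")
  np <- dim(vectors)[1]
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, np)
  stopifnot(length(valid_mask) == np, is.logical(valid_mask))
  structure(list(vectors = vectors, valid_mask = valid_mask),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  d <- dim(x$vectors)
  mag <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2)
  cat(sprintf(
    "flow_field: %d frame pairs of %d x %d (%d valid), max |v| = %.3f px\n",
    d[1], d[2], d[3], sum(x$valid_mask), max(mag)))
  invisible(x)
}

# Horn-Schunck neighbour average with the classical 1/6-1/12 stencil,
# replicate borders.
#' @noRd
.hs_average <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- m[.clamp(seq_len(h) - 1L, 1L, h), , drop = FALSE]
  dn <- m[.clamp(seq_len(h) + 1L, 1L, h), , drop = FALSE]
  lf <- m[, .clamp(seq_len(w) - 1L, 1L, w), drop = FALSE]
  rt <- m[, .clamp(seq_len(w) + 1L, 1L, w), drop = FALSE]
  ul <- up[, .clamp(seq_len(w) - 1L, 1L, w), drop = FALSE]
  ur <- up[, .clamp(seq_len(w) + 1L, 1L, w), drop = FALSE]
  dl <- dn[, .clamp(seq_len(w) - 1L, 1L, w), drop = FALSE]
  drr <- dn[, .clamp(seq_len(w) + 1L, 1L, w), drop = FALSE]
  (up + dn + lf + rt) / 6 + (ul + ur + dl + drr) / 12
}

# Single-pair coarse-to-fine Horn-Schunck. src and dst are H x W matrices
# on a 0..255 intensity scale; returns list(vr, vc).
#' @noRd
.hs_pair <- function(src, dst, n_levels, iterations, alpha) {
  h <- nrow(src); w <- ncol(src)
  # pyramid sizes, coarse to fine; never below 8 px
  sizes <- list()
  for (l in (n_levels - 1):0) {
    hs <- max(8L, round(h / 2^l)); ws <- max(8L, round(w / 2^l))
    sizes[[length(sizes) + 1L]] <- c(hs, ws)
  }
  sizes <- unique(sizes)
  vr <- matrix(0, sizes[[1]][1], sizes[[1]][2])
  vc <- matrix(0, sizes[[1]][1], sizes[[1]][2])
  a2 <- alpha^2
  for (si in seq_along(sizes)) {
    hs <- sizes[[si]][1]; ws <- sizes[[si]][2]
    # anti-alias smoothing proportional to the downsampling factor
    sc_f <- h / hs
    smooth_level <- function(m) {
      if (sc_f > 1) m <- .gaussian_smooth(m, 0.6 * sqrt(sc_f^2 - 1))
      if (hs == h && ws == w) m else .bicubic_resize(m, hs, ws)
    }
    A <- smooth_level(dst)
    B <- smooth_level(src)
    if (si > 1L) {
      sr <- hs / nrow(vr); sc <- ws / ncol(vc)
      vr <- .bicubic_resize(vr, hs, ws) * sr
      vc <- .bicubic_resize(vc, hs, ws) * sc
    }
    # warp source by current flow, then solve for the increment
    rows <- matrix(seq_len(hs), hs, ws)
    cols <- matrix(seq_len(ws), hs, ws, byrow = TRUE)
    Bw <- matrix(.bilinear_sample(B, as.vector(rows + vr),
                                  as.vector(cols + vc)), hs, ws)
    gA <- .central_gradient(A); gB <- .central_gradient(Bw)
    Ix <- (gA$dr + gB$dr) / 2
    Ic <- (gA$dc + gB$dc) / 2
    It <- Bw - A
    denom <- a2 + Ix^2 + Ic^2
    du <- matrix(0, hs, ws); dv <- matrix(0, hs, ws)
    for (it in seq_len(iterations)) {
      du_a <- .hs_average(du); dv_a <- .hs_average(dv)
      term <- (Ix * du_a + Ic * dv_a + It) / denom
      du <- du_a - Ix * term
      dv <- dv_a - Ic * term
    }
    # median filtering between levels suppresses outliers at texture-poor
    # boundaries (standard practice in pyramidal flow solvers)
    vr <- .median3(vr + du)
    vc <- .median3(vc + dv)
  }
  list(vr = vr, vc = vc)
}

#' Estimate dense optical flow for a cine sequence
#'
#' Runs a deterministic coarse-to-fine Horn-Schunck variational solver on
#' every consecutive frame pair (frame skip 1). Intensities are scaled to
#' 0-255 internally so the `smoothness` weight matches classical
#' Horn-Schunck practice. The returned field follows the backward-warp
#' convention described in [flow_field()]: `warp(frame[t], v_t)`
#' approximates `frame[t + 1]`.
#'
#' @param seq A [cine_sequence()] with at least 2 frames.
#' @param n_levels Pyramid levels (>= 1), default 3.
#' @param iterations Jacobi iterations per level, default 50.
#' @param smoothness Horn-Schunck regularisation weight alpha on the 0-255
#'   intensity scale, default 15.
#' @return A [flow_field()] with one `(drow, dcol)` field per pair.
#' @export
estimate_flow <- function(seq, n_levels = 3L, iterations = 50L,
                          smoothness = 15) {
  stopifnot(inherits(seq, "cine_sequence"), n_levels >= 1, iterations >= 1,
            smoothness > 0)
  d <- dim(seq$frames); T <- d[1]; h <- d[2]; w <- d[3]
  out <- array(0, c(T - 1, h, w, 2))
  warned <- FALSE
  for (t in seq_len(T - 1)) {
    src <- seq$frames[t, , ] * 255
    dst <- seq$frames[t + 1, , ] * 255
    if (stats::sd(src) == 0 && stats::sd(dst) == 0) {
      if (!warned) {
        warning("constant (zero-variance) frame pair(s): returning zero flow")
        warned <- TRUE
      }
      next
    }
    v <- .hs_pair(src, dst, n_levels, iterations, smoothness)
    out[t, , , 1] <- v$vr
    out[t, , , 2] <- v$vc
  }
  flow_field(out)
}

#' Backward-warp a frame along a flow field
#'
#' Samples `frame` at `(r + drow, c + dcol)` with bilinear interpolation;
#' out-of-bounds samples take the border value. Under the package's flow
#' convention this aligns frame `t` onto the grid of frame `t + 1`.
#'
#' @param frame `H x W` numeric matrix.
#' @param flow `H x W x 2` array of `(drow, dcol)` displacements.
#' @return The warped `H x W` matrix.
#' @export
warp <- function(frame, flow) {
  stopifnot(is.matrix(frame), is.array(flow), length(dim(flow)) == 3,
            dim(flow)[3] == 2, all(dim(flow)[1:2] == dim(frame)))
  if (!all(is.finite(flow))) stop("flow must be finite")
  h <- nrow(frame); w <- ncol(frame)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  matrix(.bilinear_sample(frame, as.vector(rows + flow[, , 1]),
                          as.vector(cols + flow[, , 2])), h, w)
}
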