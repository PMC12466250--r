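# Reading and writing cine sequences: NIfTI volumes (time as the third
# axis, the cardiac-MRI convention used throughout) or directories of
# lexicographically ordered PNG frames.

#' Read a cine sequence from NIfTI or a PNG frame directory
#'
#' A `.nii`/`.nii.gz` file is read as an `H x W x T` volume (time on the
#' third axis); a directory is read as lexicographically ordered
#' `.png`/`.PNG` frames. Intensities are min-max normalized to `[0, 1]`
#' unless `normalize = FALSE` (in which case they must already lie in
#' `[0, 1]`).
#'
#' @param path NIfTI file or frame directory.
#' @param normalize Min-max normalize intensities (default `TRUE`).
#' @return A [cine_sequence()].
#' @export
read_sequence <- function(path, normalize = TRUE) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0)
      stop(sprintf("no frames found in directory '%s'", path))
    frames_list <- lapply(files, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3) img <- apply(img[, , 1:3, drop = FALSE],
                                              c(1, 2), mean)
      img
    })
    dims <- vapply(frames_list, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("mixed frame shapes in directory")
    arr <- array(0, c(length(files), dims[1, 1], dims[2, 1]))
    for (t in seq_along(frames_list)) arr[t, , ] <- frames_list[[t]]
  } else if (file.exists(path)) {
    vol <- tryCatch(RNifti::readNifti(path),
                    error = function(e)
                      stop(sprintf("cannot read '%s': %s", path,
                                   conditionMessage(e))))
    vol <- as.array(vol)
    if (length(dim(vol)) != 3)
      stop(sprintf("'%s' is not a 3-D (H x W x T) volume", path))
    arr <- aperm(vol, c(3, 1, 2))
  } else {
    stop(sprintf("unreadable path '%s'", path))
  }
  if (normalize) {
    rng <- range(arr)
    if (diff(rng) > 0) arr <- (arr - rng[1]) / diff(rng)
    else arr[] <- 0
  }
  cine_sequence(arr)
}

#' Write a cine sequence as NIfTI or a PNG stack
#'
#' A path ending in `.nii`/`.nii.gz` is written as an `H x W x T` float
#' volume (round trip is exact to within `1e-6`); any other path is
#' treated as a directory of numbered 8-bit PNG frames.
#'
#' @param seq A [cine_sequence()].
#' @param path Output file or directory.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "cine_sequence"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(aperm(seq$frames, c(2, 3, 1)), path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    T <- dim(seq$frames)[1]
    for (t in seq_len(T)) {
      png::writePNG(seq$frames[t, , ],
                    file.path(path, sprintf("frame_%03d.png", t)))
    }
  }
  invisible(path)
}

#' Write an integer label map as NIfTI
#'
#' Noise (-1) is stored as -1; cluster labels keep their 0-based values.
#'
#' @param labels `H x W` integer matrix.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(is.matrix(labels))
  RNifti::writeNifti(array(as.numeric(labels), c(dim(labels), 1)), path)
  invisible(path)
}
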