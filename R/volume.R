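#' 3D voxel map with physical voxel size
#'
#' A `volume_map` is the carrier for every image and parameter map in the
#' pipeline: a 3D numeric (or complex) array with a physical voxel size in
#' millimetres attached. Invalid voxels are encoded as `NA`.
#'
#' @param data 3D array of voxel values.
#' @param voxel_mm voxel size in mm; a single number or a length-3 vector.
#' @return A `volume_map` object.
#' @export
volume_map <- function(data, voxel_mm = c(1, 1, 1)) {
  if (length(dim(data)) != 3L)
    stop("volume_map requires a 3D array, got ", length(dim(data)), " dims")
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  if (any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("voxel size must be positive and finite")
  structure(unclass(data), voxel_mm = voxel_mm,
            class = c("volume_map", "array"))
}

#' @export
print.volume_map <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("volume_map: %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], voxel_mm(x)[1], voxel_mm(x)[2], voxel_mm(x)[3]))
  v <- x[!is.na(x)]
  if (is.complex(v)) v <- Mod(v)
  if (length(v))
    cat(sprintf("  range [%.4g, %.4g], %d invalid voxels\n",
                min(v), max(v), sum(is.na(x))))
  invisible(x)
}

#' Voxel size of a volume map
#' @param x a `volume_map` (or array with a `voxel_mm` attribute).
#' @return Length-3 numeric vector of voxel sizes in mm.
#' @export
voxel_mm <- function(x) {
  v <- attr(x, "voxel_mm")
  if (is.null(v)) c(1, 1, 1) else v
}

# Rewrap an array with the metadata of a template volume_map. Arithmetic on
# volume_map drops attributes, so internal code rewraps results explicitly.
rewrap <- function(data, template) volume_map(data, voxel_mm(template))

#' Read a 3D map from a NIfTI-1 file
#'
#' Voxel size is taken from the header; invalid voxels arrive as `NaN` and
#' are converted to `NA`.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume_map].
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), " dimensions in ", path)
  arr <- array(as.numeric(img), dim = d)
  arr[is.nan(arr)] <- NA_real_
  volume_map(arr, RNifti::pixdim(img)[seq_len(3)])
}

#' Write a 3D map to a NIfTI-1 file
#'
#' Written as float64 so that voxel values and `NA` (stored as `NaN`)
#' round-trip exactly.
#'
#' @param x a [volume_map].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_map <- function(x, path) {
  if (length(dim(x)) != 3L) stop("only 3D volumes are written")
  arr <- unclass(x)
  attributes(arr) <- list(dim = dim(x))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_mm(x)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Block-average a map onto a coarser grid
#'
#' Used to harmonize proton-resolution maps (WF, ECV) to the sodium grid
#' before model inversion: each coarse voxel is the mean of a
#' `factor^3` block, which matches the physical direction of partial
#' voluming. `NA` voxels are ignored inside a block; a block that is all
#' `NA` stays `NA`.
#'
#' @param x a [volume_map] whose dimensions are divisible by `factor`.
#' @param factor integer down-sampling factor per axis.
#' @return A [volume_map] with `factor`-times larger voxels.
#' @export
block_average <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(x)
  d <- dim(x)
  if (any(d %% factor != 0L))
    stop("dimensions ", paste(d, collapse = "x"),
         " not divisible by factor ", factor)
  dn <- d %/% factor
  a <- array(unclass(x), dim = c(factor, dn[1], factor, dn[2], factor, dn[3]))
  s <- apply(a, c(2, 4, 6), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  volume_map(s, voxel_mm(x) * factor)
}

# Majority-vote block reduction for integer label volumes.
block_mode <- function(labels, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(labels)
  d <- dim(labels)
  dn <- d %/% factor
  a <- array(labels, dim = c(factor, dn[1], factor, dn[2], factor, dn[3]))
  apply(a, c(2, 4, 6), function(v) {
    tb <- tabulate(v + 1L)
    which.max(tb) - 1L
  })
}

# FFT-based Gaussian smoothing with periodic boundaries. fwhm in mm per
# axis; NA voxels are treated as 0 with mass renormalization.
gaussian_smooth <- function(x, fwhm_mm) {
  if (all(fwhm_mm <= 0)) return(x)
  d <- dim(x)
  vx <- voxel_mm(x)
  sigma <- rep_len(fwhm_mm, 3L) / (2 * sqrt(2 * log(2)))
  arr <- unclass(x)
  attributes(arr) <- list(dim = d)
  na <- is.na(arr)
  w <- array(1, d); w[na] <- 0
  arr[na] <- 0
  filt <- array(1, d)
  for (ax in 1:3) {
    f <- fft_freq(d[ax]) / (d[ax] * vx[ax])   # cycles per mm
    g <- exp(-2 * pi^2 * sigma[ax]^2 * f^2)
    filt <- filt * outer_axis(g, d, ax)
  }
  sm <- Re(stats::fft(stats::fft(arr) * filt, inverse = TRUE)) / prod(d)
  if (any(na)) {
    smw <- Re(stats::fft(stats::fft(w) * filt, inverse = TRUE)) / prod(d)
    out <- sm / pmax(smw, .Machine$double.eps)
    out[na & smw < 1e-6] <- NA_real_
  } else {
    out <- sm
  }
  rewrap(out, x)
}

# FFT sample frequencies in cycles per array length (integer k index).
fft_freq <- function(n) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  as.numeric(k)
}

# Broadcast a per-axis vector g (length d[ax]) into a full 3D array.
outer_axis <- function(g, d, ax) {
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- array(g, dim = c(d[ax], d[-ax]))
  aperm(a, order(perm))
}

#' Erode a binary mask
#'
#' Morphological erosion with the 6-connected structuring element,
#' iterated. Used to take interior gel/tissue ROIs that exclude
#' partial-volume edge voxels.
#'
#' @param mask logical 3D array.
#' @param iterations number of one-voxel erosion passes.
#' @return Logical 3D array.
#' @export
erode_mask <- function(mask, iterations = 1) {
  m <- as.array(mask)
  d <- dim(m)
  for (i in seq_len(iterations)) {
    s <- m
    s[-1, , ] <- s[-1, , ] & m[-d[1], , ]
    s[-d[1], , ] <- s[-d[1], , ] & m[-1, , ]
    s[, -1, ] <- s[, -1, ] & m[, -d[2], ]
    s[, -d[2], ] <- s[, -d[2], ] & m[, -1, ]
    s[, , -1] <- s[, , -1] & m[, , -d[3]]
    s[, , -d[3]] <- s[, , -d[3]] & m[, , -1]
    m <- s
  }
  m
}

#' ROI statistics
#'
#' Mean, sample SD and valid-voxel count of a map over a region of
#' interest, the form in which voxel maps are reported (mean +/- SD over an
#' N-voxel ROI). Invalid (`NA`) voxels are excluded and counted.
#'
#' @param map a [volume_map].
#' @param roi logical mask of the same dimensions.
#' @return List with `mean`, `sd`, `n` (valid voxels) and `n_invalid`.
#' @export
roi_stats <- function(map, roi) {
  roi <- as.logical(roi)
  if (!any(roi, na.rm = TRUE)) stop("ROI is empty")
  v <- unclass(map)[which(roi)]
  bad <- is.na(v)
  v <- v[!bad]
  if (!length(v)) stop("ROI contains no valid voxels")
  list(mean = mean(v), sd = stats::sd(v), n = length(v),
       n_invalid = sum(bad))
}
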