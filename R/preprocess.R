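#' Percentile histogram stretch to the unit interval
#'
#' Linearly rescales an image so that the `p_low`-th percentile of the
#' foreground maps to 0 and the `p_high`-th maps to 1, clipping outside
#' values. Percentiles are computed over foreground pixels only; background
#' (e.g. a manually thresholded area) is excluded via `background_mask`.
#' The map is monotone in the input.
#'
#' @param image 2-D numeric matrix.
#' @param background_mask optional logical/0-1 matrix, `TRUE`/1 where the
#'   pixel is background; `NULL` means all pixels are foreground.
#' @param p_low,p_high percentiles in \[0,100\], `p_low < p_high`.
#' @return matrix of the same shape with values in \[0,1\].
#' @export
histogram_stretch <- function(image, background_mask = NULL,
                              p_low = 1, p_high = 99) {
  stopifnot(is.matrix(image), p_low < p_high)
  fg <- if (is.null(background_mask)) rep(TRUE, length(image))
        else !(as.logical(background_mask))
  if (!any(fg)) stop("histogram_stretch: image is all background")
  q <- quantile(image[fg], c(p_low, p_high) / 100, names = FALSE, type = 7)
  if (q[1] == q[2]) {
    warning("histogram_stretch: degenerate percentiles (constant foreground); returning zeros")
    return(image * 0)
  }
  clip01((image - q[1]) / (q[2] - q[1]))
}

# rasterized Euclidean disk structuring element of the given pixel radius
disc_kernel <- function(radius) {
  d <- 2 * radius + 1
  outer(seq_len(d), seq_len(d), function(i, j)
    (i - radius - 1)^2 + (j - radius - 1)^2 <= radius^2 + 1e-9) * 1L
}

# centroid of a binary mask: c(row, col)
mask_centroid <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

#' Extract orientation-ready single-cell crops from a label mask
#'
#' For each positive label in `label_mask`: the label's region is dilated by
#' `ring_dilation_px` (disk structuring element) to form a ring/cell mask —
#' emulating the nuclear-mask dilation used to build cell ring masks — but is
#' not allowed to absorb pixels belonging to other labels. A
#' `crop_size x crop_size` crop centered on the mask centroid is cut from the
#' image stack (zero-padded at borders) and pixels outside the cell mask are
#' zeroed.
#'
#' @param image_stack `channels x H x W` array, values in \[0,1\].
#' @param label_mask `H x W` integer matrix; 0 is background.
#' @param crop_size crop side in pixels.
#' @param ring_dilation_px dilation radius in pixels (default 3).
#' @param marker_names optional channel names.
#' @return list of [single_cell_image()] in increasing label order; empty
#'   labels are skipped with a message.
#' @export
extract_single_cells <- function(image_stack, label_mask, crop_size,
                                 ring_dilation_px = 3,
                                 marker_names = NULL) {
  stopifnot(length(dim(image_stack)) == 3,
            all(dim(image_stack)[2:3] == dim(label_mask)))
  n_ch <- dim(image_stack)[1]
  if (is.null(marker_names)) marker_names <- sprintf("M%02d", seq_len(n_ch))
  labels <- sort(setdiff(unique(as.vector(label_mask)), 0))
  brush <- disc_kernel(ring_dilation_px)
  out <- list()
  for (lb in labels) {
    region <- (label_mask == lb) * 1L
    if (!sum(region)) { message("skipping empty label ", lb); next }
    dil <- EBImage::dilate(region, brush) != 0
    mask <- dil & (label_mask == 0 | label_mask == lb)
    ctr <- round(mask_centroid(mask))
    half <- floor(crop_size / 2)
    rows <- (ctr[1] - half):(ctr[1] + half - 1 + crop_size %% 2)
    cols <- (ctr[2] - half):(ctr[2] + half - 1 + crop_size %% 2)
    crop_mask <- matrix(0L, crop_size, crop_size)
    px <- array(0, c(n_ch, crop_size, crop_size))
    ok_r <- rows >= 1 & rows <= nrow(label_mask)
    ok_c <- cols >= 1 & cols <= ncol(label_mask)
    crop_mask[ok_r, ok_c] <- mask[rows[ok_r], cols[ok_c]] * 1L
    for (ch in seq_len(n_ch)) {
      m <- matrix(0, crop_size, crop_size)
      m[ok_r, ok_c] <- image_stack[ch, , ][rows[ok_r], cols[ok_c]]
      px[ch, , ] <- m * crop_mask
    }
    out[[length(out) + 1]] <- single_cell_image(
      clip01(px), crop_mask, cell_id = sprintf("cell_%05d", lb),
      marker_names = marker_names, metadata = list(label = lb))
  }
  out
}

# orientation of a binary mask from second central moments, radians in
# (-pi/2, pi/2]; 0 for (near-)circular masks (tie-break)
mask_orientation <- function(mask, eps = 1e-9) {
  idx <- which(mask != 0, arr.ind = TRUE)
  y <- idx[, 1] - mean(idx[, 1])   # rows
  x <- idx[, 2] - mean(idx[, 2])   # cols
  mu20 <- mean(x^2); mu02 <- mean(y^2); mu11 <- mean(x * y)
  if (abs(mu20 - mu02) < eps && abs(mu11) < eps) return(0)
  0.5 * atan2(2 * mu11, mu20 - mu02)
}

# sample image m at rotated coordinates: rotation by angle theta about the
# crop center, bilinear or nearest interpolation, zero fill outside
rotate_image <- function(m, theta, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  n_r <- nrow(m); n_c <- ncol(m)
  cy <- (n_r + 1) / 2; cx <- (n_c + 1) / 2
  rr <- matrix(seq_len(n_r), n_r, n_c) - cy
  cc <- matrix(seq_len(n_c), n_r, n_c, byrow = TRUE) - cx
  # destination pixel (y,x) samples the source at the +theta-rotated offset
  sx <- cc * cos(theta) - rr * sin(theta) + cx
  sy <- cc * sin(theta) + rr * cos(theta) + cy
  if (interp == "nearest") {
    si <- round(sy); sj <- round(sx)
    ok <- si >= 1 & si <= n_r & sj >= 1 & sj <= n_c
    out <- matrix(0, n_r, n_c)
    out[ok] <- m[cbind(si[ok], sj[ok])]
    return(out)
  }
  i0 <- floor(sy); j0 <- floor(sx)
  fy <- sy - i0; fx <- sx - j0
  pick <- function(i, j) {
    ok <- i >= 1 & i <= n_r & j >= 1 & j <= n_c
    v <- numeric(length(i)); v[ok] <- m[cbind(i[ok], j[ok])]
    v
  }
  v00 <- pick(i0, j0); v01 <- pick(i0, j0 + 1)
  v10 <- pick(i0 + 1, j0); v11 <- pick(i0 + 1, j0 + 1)
  out <- v00 * (1 - fy) * (1 - fx) + v01 * (1 - fy) * fx +
    v10 * fy * (1 - fx) + v11 * fy * fx
  matrix(out, n_r, n_c)
}

#' Rotate a cell so its mask's major axis is horizontal
#'
#' The mask orientation is the angle of its second-central-moment major axis;
#' the cell (pixels bilinear, mask nearest) is rotated by the negative of
#' that angle. Perfect circles are defined to have orientation 0 and are
#' returned unrotated. Intensities are re-clipped to \[0,1\].
#'
#' @param cell a `single_cell_image`.
#' @return the aligned `single_cell_image`.
#' @export
align_major_axis <- function(cell) {
  stopifnot(inherits(cell, "single_cell_image"))
  theta <- mask_orientation(cell$mask)
  if (theta == 0) return(cell)
  new_mask <- (rotate_image(cell$mask, theta, "nearest") > 0.5) * 1L
  if (!sum(new_mask)) return(cell)  # pathological: keep original
  px <- cell$pixels
  for (ch in seq_len(dim(px)[1]))
    px[ch, , ] <- clip01(rotate_image(cell$pixels[ch, , ], theta, "bilinear")) *
      new_mask
  cell$pixels <- px
  cell$mask <- new_mask
  cell
}

#' Flip a cell so a reference channel's mass centroid sits upper-left
#'
#' Flips the crop horizontally and/or vertically so the intensity-weighted
#' centroid of `reference_channel` lies in the upper-left quadrant relative
#' to the crop center, removing the residual polar-orientation nuisance after
#' [align_major_axis()]. Exactly idempotent; centroids exactly on an axis
#' trigger no flip, and a zero-mass reference channel leaves the cell
#' unchanged.
#'
#' @param cell a `single_cell_image`.
#' @param reference_channel marker name or channel index (default 1, by
#'   convention the nuclear channel).
#' @return the oriented `single_cell_image`.
#' @export
orient_by_mass <- function(cell, reference_channel = 1) {
  stopifnot(inherits(cell, "single_cell_image"))
  ch <- if (is.character(reference_channel))
    match(reference_channel, cell$marker_names) else reference_channel
  if (is.na(ch) || ch < 1 || ch > dim(cell$pixels)[1])
    stop("reference_channel not in panel")
  w <- cell$pixels[ch, , ]
  tot <- sum(w)
  if (tot == 0) { message("orient_by_mass: zero-mass reference channel; no flip"); return(cell) }
  n_r <- nrow(w); n_c <- ncol(w)
  cy <- sum(row(w) * w) / tot
  cx <- sum(col(w) * w) / tot
  flip_r <- cy > (n_r + 1) / 2
  flip_c <- cx > (n_c + 1) / 2
  if (!flip_r && !flip_c) return(cell)
  ridx <- if (flip_r) n_r:1 else seq_len(n_r)
  cidx <- if (flip_c) n_c:1 else seq_len(n_c)
  px <- cell$pixels
  for (k in seq_len(dim(px)[1])) px[k, , ] <- cell$pixels[k, ridx, cidx]
  cell$pixels <- px
  cell$mask <- cell$mask[ridx, cidx]
  cell
}

#' Mean marker intensity table from single-cell images
#'
#' Entry `(cell, marker)` is the mean of that marker's channel over the
#' cell's mask pixels.
#'
#' @param cells list of `single_cell_image` sharing one marker order.
#' @return numeric matrix, cells x markers, with cell ids as rownames.
#' @export
mean_intensity_table <- function(cells) {
  stopifnot(length(cells) > 0)
  mk <- cells[[1]]$marker_names
  vals <- matrix(0, length(cells), length(mk),
                 dimnames = list(vapply(cells, function(x)
                   as.character(x$cell_id), character(1)), mk))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    if (!identical(cell$marker_names, mk))
      stop("inconsistent marker order across cells")
    idx <- which(cell$mask != 0)
    for (j in seq_along(mk)) vals[i, j] <- mean(cell$pixels[j, , ][idx])
  }
  vals
}

#' Seeded train/test split of cells
#'
#' A seeded shuffle of cell indices split into a training fraction and the
#' held-out remainder; downstream selection and evaluation reuse the same
#' split by reusing the same seed.
#'
#' @param n_cells number of cells (or a list of cells).
#' @param train_fraction fraction assigned to training (default 0.9).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_cells <- function(n_cells, train_fraction = 0.9, seed = 1) {
  if (is.list(n_cells)) n_cells <- length(n_cells)
  stopifnot(n_cells >= 2, train_fraction > 0, train_fraction < 1)
  with_local_seed(seed, {
    perm <- sample.int(n_cells)
    n_tr <- max(1, round(train_fraction * n_cells))
    list(train = sort(perm[seq_len(n_tr)]),
         test = sort(perm[-seq_len(n_tr)]))
  })
}
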