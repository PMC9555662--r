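#' Gaussian-blur noise baseline
#'
#' Per-channel Gaussian filtering of a cell's pixels (the mask is unchanged),
#' simulating optical blur. Values are clipped back to \[0,1\]; constant
#' images are unchanged.
#'
#' @param cell a `single_cell_image`.
#' @param sigma Gaussian sd in pixels (> 0, default 1).
#' @return the blurred `single_cell_image`.
#' @export
add_gaussian_blur <- function(cell, sigma = 1) {
  stopifnot(inherits(cell, "single_cell_image"))
  if (sigma <= 0) stop("sigma must be > 0")
  px <- cell$pixels
  for (ch in seq_len(dim(px)[1]))
    px[ch, , ] <- clip01(EBImage::gblur(cell$pixels[ch, , ], sigma = sigma))
  cell$pixels <- px
  cell
}

#' Salt-and-pepper noise baseline
#'
#' Each pixel of each channel is independently replaced, with probability
#' `amount`, by 0 or 1 (equal odds), from a seeded stream. The mask is
#' unchanged.
#'
#' @param cell a `single_cell_image`.
#' @param amount fraction of pixels corrupted, in \[0,1\] (default 0.1).
#' @param seed optional integer seed.
#' @return the corrupted `single_cell_image`.
#' @export
add_salt_pepper <- function(cell, amount = 0.1, seed = NULL) {
  stopifnot(inherits(cell, "single_cell_image"),
            amount >= 0, amount <= 1)
  if (amount == 0) return(cell)
  with_local_seed(seed, {
    px <- cell$pixels
    hit <- runif(length(px)) < amount
    salt <- runif(length(px)) < 0.5
    px[hit] <- ifelse(salt[hit], 1, 0)
    cell$pixels <- px
    cell
  })
}

#' Segmentation-noise mask perturbation (half erode / half dilate)
#'
#' Splits the mask into two halves along `split_axis`, erodes one half and
#' dilates the other with a disk structuring element, and rejoins them —
#' emulating the few-pixel boundary disagreement between segmentation
#' methods. With the default vertical split, the left half is eroded and the
#' right half dilated; the choice is arbitrary but kept consistent across all
#' cells. Deterministic.
#'
#' @param mask binary matrix.
#' @param split_axis `"vertical"` (left/right halves) or `"horizontal"`
#'   (top/bottom).
#' @param radius structuring-element radius in pixels (default 1).
#' @return the perturbed binary mask.
#' @export
perturb_mask_erode_dilate <- function(mask, split_axis = c("vertical",
                                                           "horizontal"),
                                      radius = 1) {
  split_axis <- match.arg(split_axis)
  if (!sum(mask)) { warning("empty mask; returned unchanged"); return(mask) }
  brush <- disc_kernel(radius)
  er <- (EBImage::erode(mask * 1L, brush) != 0) * 1L
  di <- (EBImage::dilate(mask * 1L, brush) != 0) * 1L
  out <- mask * 1L
  if (split_axis == "vertical") {
    half <- floor(ncol(mask) / 2)
    out[, seq_len(half)] <- er[, seq_len(half)]
    out[, (half + 1):ncol(mask)] <- di[, (half + 1):ncol(mask)]
  } else {
    half <- floor(nrow(mask) / 2)
    out[seq_len(half), ] <- er[seq_len(half), ]
    out[(half + 1):nrow(mask), ] <- di[(half + 1):nrow(mask), ]
  }
  out
}

#' Re-extract a cell with a perturbed mask
#'
#' Zeroes pixels outside the new mask, simulating re-segmentation; the
#' downstream mean-intensity table then reflects the segmentation
#' disagreement.
#'
#' @param cell a `single_cell_image` (its pixels are treated as the image
#'   stack).
#' @param perturbed_mask binary matrix congruent with the cell's crop.
#' @return a `single_cell_image` using `perturbed_mask`, or `NULL` (with a
#'   message) if the mask is empty.
#' @export
reextract_with_perturbed_mask <- function(cell, perturbed_mask) {
  stopifnot(inherits(cell, "single_cell_image"),
            all(dim(perturbed_mask) == dim(cell$mask)))
  if (!sum(perturbed_mask)) {
    message("empty perturbed mask for ", cell$cell_id, "; skipped")
    return(NULL)
  }
  px <- cell$pixels
  for (ch in seq_len(dim(px)[1]))
    px[ch, , ] <- cell$pixels[ch, , ] * perturbed_mask
  single_cell_image(px, perturbed_mask, cell$cell_id, cell$marker_names,
                    cell$metadata)
}

#' Apply a named technical-noise type to a list of cells
#'
#' @param cells list of `single_cell_image`.
#' @param type `"blur"`, `"saltpepper"` or `"segmentation"`.
#' @param sigma blur sd.
#' @param amount salt-and-pepper fraction.
#' @param split_axis,radius segmentation-perturbation controls.
#' @param seed integer seed (salt-and-pepper only; one stream across cells).
#' @return list of noisy `single_cell_image` (empty re-extractions dropped).
#' @export
apply_noise <- function(cells, type = c("blur", "saltpepper", "segmentation"),
                        sigma = 1, amount = 0.1,
                        split_axis = "vertical", radius = 1, seed = 1) {
  type <- match.arg(type)
  if (type == "blur")
    return(lapply(cells, add_gaussian_blur, sigma = sigma))
  if (type == "saltpepper")
    return(with_local_seed(seed,
      lapply(cells, function(cell) add_salt_pepper(cell, amount))))
  out <- lapply(cells, function(cell) {
    pm <- perturb_mask_erode_dilate(cell$mask, split_axis, radius)
    reextract_with_perturbed_mask(cell, pm)
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Technical-noise comparison table
#'
#' Runs the three noise simulators on a set of cells and reports, for each,
#' the mean per-channel SSIM and the mean per-marker Spearman correlation of
#' mean intensities against the clean cells — the same metrics used for
#' imputation, so imputation error can be compared against accepted technical
#' variation.
#'
#' @param cells list of clean `single_cell_image`.
#' @param sigma,amount,split_axis,radius,seed noise parameters.
#' @return data.frame with one row per noise type: `noise`, `mean_ssim`,
#'   `mean_spearman`.
#' @export
noise_comparison_table <- function(cells, sigma = 1, amount = 0.1,
                                   split_axis = "vertical", radius = 1,
                                   seed = 1) {
  clean_tab <- mean_intensity_table(cells)
  all_ids <- vapply(cells, function(x) as.character(x$cell_id), character(1))
  rows <- lapply(c("blur", "saltpepper", "segmentation"), function(ty) {
    noisy <- apply_noise(cells, ty, sigma = sigma, amount = amount,
                         split_axis = split_axis, radius = radius,
                         seed = seed)
    keep <- match(vapply(noisy, function(x) as.character(x$cell_id),
                         character(1)), all_ids)
    ss <- ssim_per_channel(cells[keep], noisy)
    sp <- spearman_per_marker(clean_tab[keep, , drop = FALSE],
                              mean_intensity_table(noisy))
    data.frame(noise = ty, mean_ssim = ss$mean, mean_spearman = sp$mean_all)
  })
  do.call(rbind, rows)
}
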