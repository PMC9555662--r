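#' Specification for a synthetic multiplex single-cell image dataset
#'
#' Describes a synthetic CyCIF-like dataset with planted marker redundancy:
#' markers are partitioned into redundancy blocks that share one latent
#' expression factor per cell, so markers within a block are (noisily)
#' linearly related while markers across blocks are related only through
#' cell-type structure. Each marker also carries a subcellular localization
#' (nuclear, membrane or cytoplasmic) that controls where its channel is
#' painted inside the cell mask.
#'
#' The defaults describe an 8-marker, 4-block, 4-cell-type panel whose block
#' structure mirrors the redundancy real CyCIF panels show between, e.g.,
#' pan-cytokeratin and individual cytokeratins: one nuclear block (Hoechst,
#' LaminB1), one cytokeratin block (CK19, PanCK), one immune block (CD45,
#' CD3) and one mixed block (ECad, CD31).
#'
#' @param n_markers number of marker channels.
#' @param marker_names character vector of length `n_markers`.
#' @param nuclear_marker name of the marker flagged as the nuclear stain
#'   (forced into every reduced panel downstream).
#' @param redundancy_blocks list of integer vectors partitioning
#'   `1:n_markers`; markers in the same block share a latent factor.
#' @param within_block_noise_sd Gaussian noise sd added to each marker's
#'   scalar expression on top of its block factor.
#' @param n_cell_types number of latent cell types.
#' @param type_mean_matrix `n_cell_types x length(redundancy_blocks)` matrix
#'   of nonnegative latent-factor means (values in \[0,1\]).
#' @param localizations per-marker localization, each one of `"nuclear"`,
#'   `"membrane"`, `"cytoplasmic"`.
#' @param crop_size side of the square per-cell crop, in pixels (>= 16).
#' @param n_cells number of cells to simulate.
#' @param seed integer RNG seed; the dataset is a deterministic function of
#'   `(spec, seed)`.
#' @param factor_sd sd of the per-cell latent factor around its type mean.
#' @param texture_sd sd of the per-pixel multiplicative texture noise.
#'
#' @return an object of class `synthetic_spec`.
#' @seealso [generate_dataset()]
#' @export
synthetic_spec <- function(n_markers = 8,
                           marker_names = NULL,
                           nuclear_marker = NULL,
                           redundancy_blocks = NULL,
                           within_block_noise_sd = 0.05,
                           n_cell_types = 4,
                           type_mean_matrix = NULL,
                           localizations = NULL,
                           crop_size = 32,
                           n_cells = 2000,
                           seed = 1,
                           factor_sd = 0.06,
                           texture_sd = 0.05) {
  if (is.null(marker_names)) {
    marker_names <- if (n_markers == 8)
      c("Hoechst", "LaminB1", "CK19", "PanCK", "CD45", "CD3", "ECad", "CD31")
    else sprintf("M%02d", seq_len(n_markers))
  }
  stopifnot(length(marker_names) == n_markers, !anyDuplicated(marker_names))
  if (is.null(nuclear_marker)) nuclear_marker <- marker_names[1]
  if (!nuclear_marker %in% marker_names)
    stop("nuclear_marker must be one of marker_names")
  if (is.null(redundancy_blocks)) {
    if (n_markers %% 2 != 0)
      stop("default redundancy_blocks need an even marker count; supply blocks")
    redundancy_blocks <- split(seq_len(n_markers),
                               rep(seq_len(n_markers / 2), each = 2))
  }
  redundancy_blocks <- lapply(redundancy_blocks, as.integer)
  flat <- unname(sort(unlist(redundancy_blocks)))
  if (!identical(flat, seq_len(n_markers)))
    stop("redundancy_blocks must partition 1:n_markers (every marker in exactly one block)")
  n_blocks <- length(redundancy_blocks)
  if (is.null(type_mean_matrix)) {
    # nuclear block (holding the nuclear marker) stays bright in every type so
    # nuclei are always visible; other blocks separate the types
    base <- matrix(c(0.85, 0.80, 0.15, 0.30,
                     0.70, 0.15, 0.75, 0.25,
                     0.90, 0.35, 0.20, 0.80,
                     0.60, 0.55, 0.60, 0.15), 4, 4, byrow = TRUE)
    type_mean_matrix <- matrix(0.15, n_cell_types, n_blocks)
    type_mean_matrix[seq_len(min(4, n_cell_types)), seq_len(min(4, n_blocks))] <-
      base[seq_len(min(4, n_cell_types)), seq_len(min(4, n_blocks))]
    if (n_blocks > 4 || n_cell_types > 4) {
      # spread extra blocks/types on a deterministic grid
      for (t in seq_len(n_cell_types)) for (b in seq_len(n_blocks))
        if (t > 4 || b > 4)
          type_mean_matrix[t, b] <- 0.15 + 0.7 * (((t * 7 + b * 3) %% 9) / 8)
    }
    nb <- which(vapply(redundancy_blocks, function(ix)
      match(nuclear_marker, marker_names) %in% ix, logical(1)))
    type_mean_matrix[, nb] <- pmax(type_mean_matrix[, nb], 0.55)
  }
  type_mean_matrix <- as.matrix(type_mean_matrix)
  if (nrow(type_mean_matrix) != n_cell_types ||
      ncol(type_mean_matrix) != n_blocks)
    stop("type_mean_matrix must be n_cell_types x n_blocks")
  if (any(type_mean_matrix < 0)) stop("type_mean_matrix must be nonnegative")
  if (is.null(localizations)) {
    if (n_markers == 8 && identical(marker_names[1], "Hoechst")) {
      localizations <- c("nuclear", "nuclear", "cytoplasmic", "cytoplasmic",
                         "membrane", "membrane", "membrane", "cytoplasmic")
    } else {
      localizations <- rep(c("nuclear", "cytoplasmic", "membrane"),
                           length.out = n_markers)
      localizations[match(nuclear_marker, marker_names)] <- "nuclear"
    }
  }
  localizations <- match.arg(localizations,
                             c("nuclear", "membrane", "cytoplasmic"),
                             several.ok = TRUE)
  if (length(localizations) != n_markers)
    stop("localizations must have one entry per marker")
  if (crop_size < 16) stop("crop_size must be >= 16")
  if (within_block_noise_sd < 0) stop("within_block_noise_sd must be >= 0")
  structure(list(
    n_markers = as.integer(n_markers), marker_names = marker_names,
    nuclear_marker = nuclear_marker, redundancy_blocks = redundancy_blocks,
    within_block_noise_sd = within_block_noise_sd,
    n_cell_types = as.integer(n_cell_types),
    type_mean_matrix = type_mean_matrix, localizations = localizations,
    crop_size = as.integer(crop_size), n_cells = as.integer(n_cells),
    seed = as.integer(seed), factor_sd = factor_sd, texture_sd = texture_sd
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic_spec:", x$n_markers, "markers in",
      length(x$redundancy_blocks), "redundancy blocks,",
      x$n_cell_types, "cell types,", x$n_cells, "cells,",
      paste0(x$crop_size, "x", x$crop_size), "crops\n")
  cat("  nuclear marker:", x$nuclear_marker, "\n")
  invisible(x)
}

# marker gain within its block: deterministic, <= 1, so noiseless expressions
# are exact scalar multiples of the block factor (within-block corr = 1)
marker_gains <- function(spec) {
  g <- numeric(spec$n_markers)
  for (blk in spec$redundancy_blocks)
    g[blk] <- 1 - 0.12 * (seq_along(blk) - 1)
  g
}

#' Generate a synthetic single-cell image dataset with planted redundancy
#'
#' Simulates `spec$n_cells` cells: each cell draws a cell type, one latent
#' factor per redundancy block (Gaussian around the type mean, clipped to
#' \[0,1\]), and per-marker scalar expressions
#' `expression = factor * gain + N(0, within_block_noise_sd)`, clipped to
#' \[0,1\]. With `within_block_noise_sd = 0`, markers in the same block are
#' exact scalar multiples of each other (correlation 1). Each cell is then
#' rendered as an elliptical mask (major axis 10-20 px at the default crop)
#' with each channel painted in its marker's subcellular localization and
#' scaled by its expression.
#'
#' All randomness comes from one RNG stream seeded with `spec$seed`; all
#' scalar draws precede all rendering draws, so `render = FALSE` yields the
#' identical truth table.
#'
#' @param spec a [synthetic_spec()].
#' @param render if `FALSE`, skip image rendering (intensity-only workflows);
#'   `cells` is then an empty list.
#' @return object of class `synth_dataset`: `cells` (list of
#'   `single_cell_image`), `truth` (cells x markers intensity matrix of the
#'   generating scalar expressions), `cell_types` (integer vector),
#'   `redundancy_blocks`, and `spec`.
#' @export
generate_dataset <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_cells < spec$n_cell_types)
    stop("n_cells must be >= n_cell_types")
  with_local_seed(spec$seed, {
    n <- spec$n_cells
    n_blocks <- length(spec$redundancy_blocks)
    types <- sample.int(spec$n_cell_types, n, replace = TRUE)
    factors <- matrix(rnorm(n * n_blocks,
                            mean = spec$type_mean_matrix[types, , drop = FALSE],
                            sd = spec$factor_sd), n, n_blocks)
    factors <- clip01(factors)
    gains <- marker_gains(spec)
    block_of <- integer(spec$n_markers)
    for (b in seq_len(n_blocks)) block_of[spec$redundancy_blocks[[b]]] <- b
    expr <- factors[, block_of, drop = FALSE] *
      rep(gains, each = n)
    if (spec$within_block_noise_sd > 0)
      expr <- expr + rnorm(length(expr), sd = spec$within_block_noise_sd)
    expr <- clip01(expr)
    dimnames(expr) <- list(sprintf("cell_%05d", seq_len(n)), spec$marker_names)
    cells <- list()
    if (render) {
      cells <- vector("list", n)
      for (i in seq_len(n)) {
        cells[[i]] <- render_cell(expr[i, ], spec$localizations,
                                  spec$crop_size,
                                  texture_sd = spec$texture_sd,
                                  marker_names = spec$marker_names,
                                  cell_id = rownames(expr)[i])
        cells[[i]]$metadata$cell_type <- types[i]
      }
    }
    structure(list(cells = cells, truth = expr, cell_types = types,
                   redundancy_blocks = spec$redundancy_blocks, spec = spec),
              class = "synth_dataset")
  })
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("synth_dataset:", nrow(x$truth), "cells x", ncol(x$truth), "markers;",
      if (length(x$cells)) "rendered" else "intensity-only", "\n")
  invisible(x)
}

#' Construct a single-cell image object
#'
#' @param pixels `channels x height x width` array with values in \[0,1\].
#' @param mask `height x width` binary (0/1) matrix; must be nonempty.
#' @param cell_id identifier.
#' @param marker_names one name per channel.
#' @param metadata free-form list (core, subtype, cell type, ...).
#' @return object of class `single_cell_image`.
#' @export
single_cell_image <- function(pixels, mask, cell_id, marker_names,
                              metadata = list()) {
  pixels <- as.array(pixels)
  stopifnot(length(dim(pixels)) == 3,
            dim(pixels)[1] == length(marker_names),
            all(dim(pixels)[2:3] == dim(mask)))
  if (!sum(mask)) stop("mask is empty")
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 1)
    stop("pixels must be finite and in [0,1]")
  structure(list(pixels = pixels, mask = (mask != 0) * 1L,
                 cell_id = cell_id, marker_names = marker_names,
                 metadata = metadata),
            class = "single_cell_image")
}

#' @export
print.single_cell_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("single_cell_image", x$cell_id, ":", d[1], "channels,",
      paste0(d[2], "x", d[3]), "px, mask area", sum(x$mask), "\n")
  invisible(x)
}

#' Render one synthetic cell from scalar marker expressions
#'
#' Paints an elliptical cell mask (random eccentricity and orientation drawn
#' from the current RNG stream, or from `shape_seed` if given) and fills each
#' channel according to its marker's localization: nuclear channels paint an
#' inner ellipse, membrane channels a ~2 px band at the mask boundary,
#' cytoplasmic channels the mask minus the nucleus. Painted pixels carry
#' multiplicative Gaussian texture noise and are clipped to \[0,1\]; an
#' expression of exactly 0 leaves its channel all-zero.
#'
#' @param expressions numeric vector in \[0,1\], one per marker.
#' @param localizations per-marker localization strings.
#' @param crop_size crop side in pixels.
#' @param shape_seed optional integer; if given, the cell's shape and texture
#'   are drawn from a local RNG stream with this seed.
#' @param texture_sd sd of multiplicative texture noise.
#' @param nucleus_frac linear scale of the nuclear ellipse relative to the
#'   cell ellipse.
#' @param marker_names,cell_id passed through to [single_cell_image()].
#' @return a `single_cell_image`.
#' @export
render_cell <- function(expressions, localizations, crop_size,
                        shape_seed = NULL, texture_sd = 0.05,
                        nucleus_frac = 0.55,
                        marker_names = names(expressions),
                        cell_id = "cell") {
  if (any(expressions < 0 | expressions > 1))
    stop("expressions must lie in [0,1]")
  if (is.null(marker_names))
    marker_names <- sprintf("M%02d", seq_along(expressions))
  with_local_seed(shape_seed, {
    a_max <- min(10, crop_size / 2 - 3)
    if (a_max < 2.5) stop("crop too small for the cell ellipse")
    a_min <- max(2.5, min(5, a_max - 1))
    a <- runif(1, a_min, a_max)                   # semi-major, 10-20 px major axis
    ecc <- runif(1, 0.2, 0.8)
    b <- max(a * sqrt(1 - ecc^2), 2.2)
    phi <- runif(1, 0, pi)
    ctr <- (crop_size + 1) / 2 + runif(2, -1.5, 1.5)
    rr <- matrix(seq_len(crop_size), crop_size, crop_size)        # rows (y)
    cc <- matrix(seq_len(crop_size), crop_size, crop_size, byrow = TRUE)
    dx <- cc - ctr[2]; dy <- rr - ctr[1]
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    mask <- ((u / a)^2 + (v / b)^2 <= 1) * 1L
    an <- a * nucleus_frac; bn <- b * nucleus_frac
    nucleus <- ((u / an)^2 + (v / bn)^2 <= 1) * 1L
    inner <- EBImage::erode(mask, disc_kernel(2))
    band <- mask * (1L - (inner != 0))
    if (!sum(band)) band <- mask
    cyto <- mask * (1L - nucleus)
    if (!sum(cyto)) cyto <- mask
    if (!sum(nucleus)) nucleus <- mask
    pats <- list(nuclear = nucleus, membrane = band, cytoplasmic = cyto)
    px <- array(0, c(length(expressions), crop_size, crop_size))
    for (m in seq_along(expressions)) {
      pat <- pats[[localizations[m]]]
      idx <- which(pat != 0)
      tex <- 1 + texture_sd * rnorm(length(idx))
      ch <- matrix(0, crop_size, crop_size)
      ch[idx] <- clip01(expressions[m] * tex)
      px[m, , ] <- ch
    }
    single_cell_image(px, mask, cell_id, marker_names,
                      metadata = list(ellipse = list(a = a, b = b, phi = phi,
                                                     center = ctr)))
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes, under `out_dir`: one channel-stacked 32-bit float TIFF and one
#' 8-bit binary mask TIFF per cell (under `cells/`), `markers.csv` (columns
#' marker, is_nuclear, localization, block), `truth_intensity.csv` (cell_id
#' plus one full-precision column per marker), `cell_types.csv`, and
#' `dataset.json` (seed and generator settings). The truth table round-trips
#' exactly through [read_dataset()].
#'
#' @param dataset a `synth_dataset` with rendered cells.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the character vector of files written (the manifest).
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  if (!length(dataset$cells)) stop("dataset has no rendered cells to write")
  dir.create(file.path(out_dir, "cells"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  spec <- dataset$spec
  files <- character(0)
  for (i in seq_along(dataset$cells)) {
    cell <- dataset$cells[[i]]
    f_img <- file.path(out_dir, "cells", sprintf("cell_%05d.tif", i))
    f_msk <- file.path(out_dir, "cells", sprintf("cell_%05d_mask.tif", i))
    pages <- lapply(seq_len(dim(cell$pixels)[1]),
                    function(ch) cell$pixels[ch, , ])
    tiff::writeTIFF(pages, f_img, bits.per.sample = 32L, reduce = FALSE)
    tiff::writeTIFF(cell$mask * 1, f_msk, bits.per.sample = 8L)
    files <- c(files, f_img, f_msk)
  }
  block_of <- integer(spec$n_markers)
  for (b in seq_along(spec$redundancy_blocks))
    block_of[spec$redundancy_blocks[[b]]] <- b
  f <- file.path(out_dir, "markers.csv")
  write.csv(data.frame(marker = spec$marker_names,
                       is_nuclear = spec$marker_names == spec$nuclear_marker,
                       localization = spec$localizations,
                       block = block_of),
            f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "truth_intensity.csv")
  write_intensity_csv(dataset$truth, f)
  files <- c(files, f)
  f <- file.path(out_dir, "cell_types.csv")
  write.csv(data.frame(cell_id = rownames(dataset$truth),
                       cell_type = dataset$cell_types),
            f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "dataset.json")
  meta <- list(seed = spec$seed, n_markers = spec$n_markers,
               marker_names = spec$marker_names,
               nuclear_marker = spec$nuclear_marker,
               redundancy_blocks = spec$redundancy_blocks,
               within_block_noise_sd = spec$within_block_noise_sd,
               n_cell_types = spec$n_cell_types,
               type_mean_matrix = dataset$spec$type_mean_matrix,
               localizations = spec$localizations,
               crop_size = spec$crop_size, n_cells = spec$n_cells,
               factor_sd = spec$factor_sd, texture_sd = spec$texture_sd)
  jsonlite::write_json(meta, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `cells/`, `markers.csv`,
#'   `truth_intensity.csv`, `cell_types.csv` and `dataset.json`.
#' @return a `synth_dataset` (pixel values carry 32-bit float precision).
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  markers <- read.csv(file.path(dir, "markers.csv"))
  truth <- read_intensity_csv(file.path(dir, "truth_intensity.csv"))
  ct <- read.csv(file.path(dir, "cell_types.csv"))$cell_type
  img_files <- sort(list.files(file.path(dir, "cells"),
                               pattern = "^cell_[0-9]+\\.tif$",
                               full.names = TRUE))
  cells <- vector("list", length(img_files))
  for (i in seq_along(img_files)) {
    pages <- tiff::readTIFF(img_files[i], all = TRUE)
    px <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (ch in seq_along(pages)) px[ch, , ] <- pages[[ch]]
    msk <- tiff::readTIFF(sub("\\.tif$", "_mask.tif", img_files[i]))
    cells[[i]] <- single_cell_image(clip01(px), (msk > 0.5) * 1L,
                                    rownames(truth)[i], markers$marker,
                                    metadata = list(cell_type = ct[i]))
  }
  blocks <- meta$redundancy_blocks
  if (is.matrix(blocks)) blocks <- asplit(blocks, 1)  # json may flatten
  blocks <- lapply(blocks, as.integer)
  spec <- synthetic_spec(
    n_markers = meta$n_markers, marker_names = markers$marker,
    nuclear_marker = meta$nuclear_marker, redundancy_blocks = blocks,
    within_block_noise_sd = meta$within_block_noise_sd,
    n_cell_types = meta$n_cell_types,
    type_mean_matrix = matrix(unlist(meta$type_mean_matrix),
                              meta$n_cell_types,
                              length(blocks)),
    localizations = markers$localization, crop_size = meta$crop_size,
    n_cells = meta$n_cells, seed = meta$seed,
    factor_sd = meta$factor_sd, texture_sd = meta$texture_sd)
  structure(list(cells = cells, truth = truth, cell_types = ct,
                 redundancy_blocks = blocks, spec = spec),
            class = "synth_dataset")
}
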