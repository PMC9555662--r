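#' Write a cells x markers intensity table to CSV at full precision
#'
#' Values are formatted with 17 significant digits so doubles round-trip
#' exactly through [read_intensity_csv()]; output bytes are deterministic
#' for identical input.
#'
#' @param table numeric matrix with cell ids as rownames and marker names as
#'   colnames.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_intensity_csv <- function(table, path) {
  stopifnot(is.matrix(table), !is.null(rownames(table)),
            !is.null(colnames(table)))
  chr <- matrix(sprintf("%.17g", table), nrow(table), ncol(table))
  df <- data.frame(cell_id = rownames(table), chr, check.names = FALSE)
  colnames(df) <- c("cell_id", colnames(table))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an intensity table written by [write_intensity_csv()]
#'
#' Also accepts any CSV whose first column is `cell_id` and remaining columns
#' are numeric marker intensities.
#'
#' @param path CSV file.
#' @return numeric matrix with `cell_id` rownames and marker colnames.
#' @export
read_intensity_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  m <- vapply(df[-1], as.numeric, numeric(nrow(df)))
  m <- matrix(m, nrow = nrow(df),
              dimnames = list(ids, colnames(df)[-1]))
  if (anyNA(m)) stop("intensity table contains missing values")
  m
}

#' Read a multichannel TIFF stack as a channels x height x width array
#'
#' @param path TIFF file; each page is one channel.
#' @return numeric array `c(channels, height, width)`.
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  px <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (ch in seq_along(pages)) px[ch, , ] <- pages[[ch]]
  px
}

#' Read an integer label mask from TIFF
#'
#' Label masks written by segmentation pipelines store integer cell ids;
#' `tiff::readTIFF` rescales integer samples to \[0,1\], so values are
#' rescaled back by the sample depth.
#'
#' @param path TIFF file.
#' @return integer matrix (0 = background).
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (is.double(m) && max(m) <= 1) m <- round(m * 65535)
  matrix(as.integer(round(m)), nrow(m), ncol(m))
}
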