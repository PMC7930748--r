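# Label-image input and construction.

#' Create a LabelImage from a matrix
#'
#' @param pixels matrix of non-negative integer labels (0 = background or
#'   membrane). Rows are image rows (y), columns are x.
#' @param pixelSize physical side length of one pixel (micrometres per
#'   pixel, default 1).
#' @param exclusionMask optional logical matrix of the same dimensions
#'   marking damaged regions.
#' @return a [LabelImage-class].
#' @export
LabelImage <- function(pixels, pixelSize = 1, exclusionMask = NULL) {
    storage.mode(pixels) <- "integer"
    if (!is.null(exclusionMask)) {
        exclusionMask <- exclusionMask != 0
        storage.mode(exclusionMask) <- "logical"
    }
    new("LabelImage", pixels = pixels, pixelSize = pixelSize,
        exclusionMask = exclusionMask)
}

#' Read a segmented label image from TIFF or PNG
#'
#' Reads a single-page grayscale integer raster in which each cell carries
#' a unique positive label and background/membrane is 0. Labels are
#' preserved bit-exactly.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param pixelSize physical pixel size (micrometres per pixel).
#' @param exclusionMask optional logical matrix marking damaged regions.
#' @return a [LabelImage-class].
#' @export
readLabelImage <- function(path, pixelSize = 1, exclusionMask = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
        img <- tiff::readTIFF(path, as.is = TRUE, all = FALSE)
    } else if (ext == "png") {
        img <- png::readPNG(path)
        # png samples come back rescaled to [0,1]; recover the integer
        # labels by finding the bit depth under which all values are whole
        recovered <- NULL
        for (mx in c(255, 65535)) {
            cand <- img * mx
            if (all(abs(cand - round(cand)) < 1e-6)) {
                recovered <- round(cand)
                break
            }
        }
        if (is.null(recovered))
            stop("PNG does not decode to integer labels")
        img <- recovered
    } else stop("unsupported image format: ", ext)
    if (length(dim(img)) == 3L) {
        if (dim(img)[3L] == 1L) img <- img[, , 1L]
        else stop("multi-channel (RGB) images are not label masks")
    }
    if (!is.matrix(img)) stop("image did not decode to a 2-D array")
    if (length(img) == 0L) stop("empty image")
    if (any(img != round(img)) || any(img < 0))
        stop("label image must contain non-negative integers")
    LabelImage(img, pixelSize = pixelSize, exclusionMask = exclusionMask)
}

#' Write a LabelImage to TIFF
#'
#' Stores labels losslessly as 16- or 32-bit integer samples.
#'
#' @param img a [LabelImage-class].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
writeLabelImage <- function(img, path) {
    px <- labelPixels(img)
    bits <- if (max(px) < 2^16) 16L else 32L
    tiff::writeTIFF(px / (2^bits - 1), path, bits.per.sample = bits,
                    compression = "none", reduce = FALSE)
    invisible(path)
}
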