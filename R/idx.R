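#' Read an IDX file (MNIST dialect)
#'
#' Reads the big-endian IDX container used by the MNIST distribution:
#' a 4-byte magic number (`0x00000801` for unsigned-byte label vectors,
#' `0x00000803` for unsigned-byte image stacks), one big-endian 32-bit
#' dimension per axis, then the uint8 payload.
#'
#' @param path Path to an IDX file.
#' @return For an image file, a [raw_dataset()]-style matrix of
#'   `M x (rows*cols)` integers in `[0, 255]` with attributes `rows` and
#'   `cols` (images are flattened row-major). For a label file, an integer
#'   vector.
#' @seealso [write_idx()]
#' @export
read_idx <- function(path) {
  if (!file.exists(path)) {
    stop("IDX file does not exist: ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (magic == 0x00000801L) {
    n <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    payload <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
    if (length(payload) != n) {
      stop(sprintf("truncated IDX payload: expected %d bytes, got %d",
                   n, length(payload)))
    }
    return(as.integer(payload))
  }
  if (magic == 0x00000803L) {
    dims <- readBin(con, "integer", n = 3L, size = 4L, endian = "big")
    m <- dims[1L]; rows <- dims[2L]; cols <- dims[3L]
    expected <- m * rows * cols
    payload <- readBin(con, "integer", n = expected, size = 1L, signed = FALSE)
    if (length(payload) != expected) {
      stop(sprintf("truncated IDX payload: expected %d bytes, got %d",
                   expected, length(payload)))
    }
    # payload is row-major per image; fill the M x P matrix by row blocks
    images <- matrix(as.integer(payload), nrow = m, ncol = rows * cols,
                     byrow = TRUE)
    attr(images, "rows") <- rows
    attr(images, "cols") <- cols
    return(images)
  }
  stop(sprintf("unsupported IDX magic number: 0x%08x", magic))
}

#' Write an IDX file (MNIST dialect)
#'
#' Inverse of [read_idx()]: writes either an image stack (a matrix of
#' `M x P` values in `[0, 255]`, with `rows`/`cols` taken from attributes
#' or supplied explicitly) or an integer label vector.
#'
#' @param x Integer matrix (images) or integer vector (labels).
#' @param path Output path.
#' @param rows,cols Image dimensions; defaults to the `rows`/`cols`
#'   attributes of `x`, then to `sqrt(P)` for square images.
#' @return `path`, invisibly.
#' @export
write_idx <- function(x, path, rows = NULL, cols = NULL) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 255) || any(x != round(x))) {
    stop("IDX payload values must be integers in [0, 255]")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  if (is.matrix(x)) {
    if (is.null(rows)) rows <- attr(x, "rows")
    if (is.null(cols)) cols <- attr(x, "cols")
    if (is.null(rows) || is.null(cols)) {
      side <- sqrt(ncol(x))
      if (side != round(side)) {
        stop("rows/cols not given and image width is not square")
      }
      rows <- cols <- as.integer(side)
    }
    if (rows * cols != ncol(x)) {
      stop("rows * cols must equal the pixel count per image")
    }
    writeBin(0x00000803L, con, size = 4L, endian = "big")
    writeBin(c(nrow(x), as.integer(rows), as.integer(cols)), con,
             size = 4L, endian = "big")
    if (nrow(x) > 0L) {
      writeBin(as.raw(as.vector(t(x))), con)
    }
  } else {
    writeBin(0x00000801L, con, size = 4L, endian = "big")
    writeBin(length(x), con, size = 4L, endian = "big")
    if (length(x) > 0L) writeBin(as.raw(as.integer(x)), con)
  }
  invisible(path)
}

#' Bundle images and labels into a raw dataset
#'
#' @param images `M x P` integer matrix with values in `[0, 255]`.
#' @param labels Integer vector of length `M` with values in `[0, 9]`.
#' @return A `raw_dataset` list with elements `images` and `labels`.
#' @export
raw_dataset <- function(images, labels) {
  stopifnot(is.matrix(images), nrow(images) == length(labels))
  if (any(images < 0) || any(images > 255)) {
    stop("pixel values must lie in [0, 255]")
  }
  structure(list(images = images, labels = as.integer(labels)),
            class = "raw_dataset")
}

#' @export
print.raw_dataset <- function(x, ...) {
  cat(sprintf("<raw_dataset> %d examples x %d pixels, %d classes\n",
              nrow(x$images), ncol(x$images), length(unique(x$labels))))
  invisible(x)
}
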