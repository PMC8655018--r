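#' 2D density map
#'
#' A square gridded intensity map with a physical pixel size. The grid center
#' convention used throughout is pixel index `floor(n/2) + 1` (1-based), so
#' integer pixel shifts are exactly representable.
#'
#' @param values Square numeric matrix.
#' @param pixel_size Pixel size in angstrom per pixel.
#' @return An object of class `density_map2d`.
#' @export
density_map2d <- function(values, pixel_size = 1) {
  values <- as.matrix(values)
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("density_map2d: zero-sized grid", call. = FALSE)
  }
  if (nrow(values) != ncol(values)) {
    stop("density_map2d: grid must be square", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("density_map2d: non-finite values", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("density_map2d: pixel_size must be a positive scalar", call. = FALSE)
  }
  structure(list(values = values, pixel_size = as.numeric(pixel_size)),
            class = "density_map2d")
}

#' @export
print.density_map2d <- function(x, ...) {
  cat(sprintf("<density_map2d> %d x %d px @ %.3g A/px, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Write a 2D density map
#'
#' Two formats: `"text"` is a portable whitespace grid with a two-line header
#' (`# bamdyn map2d` and `# nx ny pixel_size`); `"mrc"` is a minimal MRC2014
#' mode-2 (32-bit float) volume of depth 1, with the pixel size recorded in
#' the cell dimensions. Values survive either round trip to 32-bit float
#' precision or better.
#'
#' @param map A [density_map2d()].
#' @param path Output file.
#' @param format `"text"` or `"mrc"`.
#' @return `path`, invisibly.
#' @export
write_map2d <- function(map, path, format = c("text", "mrc")) {
  stopifnot(inherits(map, "density_map2d"))
  format <- match.arg(format)
  n <- nrow(map$values)
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# bamdyn map2d",
                 sprintf("# %d %d %.10g", n, n, map$pixel_size)), con)
    utils::write.table(format(map$values, digits = 9, trim = TRUE,
                              scientific = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    # MRC2014 header: 1024 bytes, mode 2, nz = 1
    hdr <- integer(256)
    hdr[1:3] <- c(n, n, 1L)              # nx ny nz
    hdr[4] <- 2L                         # mode: float32
    hdr[8:10] <- c(n, n, 1L)             # mx my mz
    writeBin(hdr[1:10], con, size = 4L, endian = "little")
    writeBin(c(n * map$pixel_size, n * map$pixel_size, map$pixel_size,
               90, 90, 90), con, size = 4L, endian = "little")  # cell, angles
    writeBin(c(1L, 2L, 3L), con, size = 4L, endian = "little")  # axis order
    writeBin(c(min(map$values), max(map$values), mean(map$values)),
             con, size = 4L, endian = "little")
    writeBin(integer(256 - 10 - 6 - 3 - 3), con, size = 4L, endian = "little")
    writeBin(as.numeric(map$values), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a 2D density map written by [write_map2d()]
#' @param path File path.
#' @param format `"auto"` (sniffs the text header), `"text"` or `"mrc"`.
#' @return A [density_map2d()].
#' @export
read_map2d <- function(path, format = c("auto", "text", "mrc")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_map2d: no such file: ", path,
                               call. = FALSE)
  if (format == "auto") {
    first <- readBin(path, "raw", n = 13L)
    format <- if (identical(rawToChar(first), "# bamdyn map2d") ||
                  identical(rawToChar(first[1:2]), "# ")) "text" else "mrc"
  }
  if (format == "text") {
    header <- readLines(path, n = 2L)
    meta <- strsplit(sub("^# *", "", header[2L]), " +")[[1L]]
    n <- as.integer(meta[1L])
    px <- as.numeric(meta[3L])
    vals <- scan(path, comment.char = "#", quiet = TRUE)
    density_map2d(matrix(vals, nrow = n, byrow = TRUE), pixel_size = px)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    dims <- readBin(con, "integer", n = 4L, size = 4L, endian = "little")
    invisible(readBin(con, "integer", n = 6L, size = 4L, endian = "little"))
    cell <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
    invisible(readBin(con, "raw", n = 1024L - 4L * 13L))
    vals <- readBin(con, "numeric", n = dims[1L] * dims[2L] * dims[3L],
                    size = 4L, endian = "little")
    density_map2d(matrix(vals, nrow = dims[1L], ncol = dims[2L]),
                  pixel_size = cell[3L])
  }
}
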