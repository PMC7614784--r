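## Shared format readers/writers: float TIFF, PNG, MRC (mode 2), CSV with
## schema checking, kymograph bundles (TIFF pages + JSON sidecar + truth CSV).
##
## Conventions: CSV is comma-separated, header row, UTF-8, '.' decimal, units
## embedded in column names; coordinates are 0-based and intervals half-open
## in every file format.

#' Read a raster image
#'
#' Reads TIFF (single- or multi-page, grayscale), PNG, or MRC (mode 2,
#' 32-bit float, per the MRC2014 standard) images. For MRC the pixel size is
#' taken from the cell dimensions in the header when present.
#'
#' @param path input file; the format is chosen by extension.
#' @return list with `data` (a matrix, or list of matrices for a multi-page
#'   TIFF) and `pixel_size_A` (`NA` when the format carries no calibration).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3L)
      p[, , 1L] else p)
    side <- paste0(path, ".scale.json")
    if (file.exists(side)) {
      sc <- jsonlite::read_json(side, simplifyVector = TRUE)
      pages <- lapply(pages, function(p) p * sc$scale + sc$offset)
    }
    list(data = if (length(pages) == 1L) pages[[1L]] else pages,
         pixel_size_A = NA_real_)
  } else if (ext == "png") {
    p <- png::readPNG(path)
    list(data = if (length(dim(p)) == 3L) p[, , 1L] else p,
         pixel_size_A = NA_real_)
  } else if (ext == "mrc") {
    read_mrc(path)
  } else {
    stop(sprintf("unrecognized image extension '%s'", ext))
  }
}

# Minimal MRC2014 reader, mode 2 (32-bit float) only. Header: 1024 bytes;
# words 1-3 = nx, ny, nz (int32 LE), word 4 = mode, words 11-13 = cell
# dimensions in Angstrom. Pixel size = cella_x / nx.
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nx <- hdr_int[1L]; ny <- hdr_int[2L]; nz <- hdr_int[3L]
  mode <- hdr_int[4L]
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  if (mode != 2L)
    stop(sprintf("unsupported MRC mode %d (only mode 2 float)", mode))
  if (nx <= 0 || ny <= 0 || nz <= 0 || nx > 1e5 || ny > 1e5)
    stop("corrupt MRC header: implausible dimensions")
  seek(con, 1024L)
  vals <- readBin(con, "numeric", n = nx * ny, size = 4L, endian = "little")
  if (length(vals) < nx * ny) stop("corrupt MRC file: truncated data")
  px <- if (cella[1L] > 0) cella[1L] / nx else NA_real_
  # MRC stores rows fastest along x; map to an R matrix with rows = y
  list(data = t(matrix(vals, nrow = nx, ncol = ny)), pixel_size_A = px)
}

#' Write a raster image
#'
#' Writes a numeric matrix (or list of matrices as a multi-page image) to
#' 32-bit float TIFF, or to PNG (values clipped to `[0, 1]`). TIFF sample
#' values are stored affinely rescaled to `[0, 1]` with the scale recorded in
#' a `<path>.scale.json` sidecar that [read_image()] reverses, so the
#' round-trip is lossless to 32-bit float precision.
#'
#' @param data matrix or list of matrices.
#' @param path output path; `.tif`/`.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(data, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    what <- if (is.matrix(data)) list(data) else data
    lo <- min(vapply(what, min, numeric(1)))
    hi <- max(vapply(what, max, numeric(1)))
    scale <- if (hi > lo) hi - lo else 1
    what <- lapply(what, function(p) (p - lo) / scale)
    tiff::writeTIFF(what, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(scale = scale, offset = lo),
                         paste0(path, ".scale.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (ext == "png") {
    png::writePNG(pmin(pmax(data, 0), 1), path)
  } else {
    stop(sprintf("unrecognized image extension '%s'", ext))
  }
  invisible(path)
}

#' Read a CSV table with schema checking
#'
#' @param path CSV file (comma, header, UTF-8).
#' @param required character vector of required column names; a missing
#'   column raises an error naming it.
#' @return data.frame.
#' @export
read_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop(sprintf("missing required column(s): %s",
                   paste(missing, collapse = ", ")))
  }
  df
}

#' Write a CSV table
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a simulated kymograph bundle
#'
#' Writes each channel as a 32-bit float TIFF page, the generating parameters
#' as a JSON sidecar, and (when ground truth is given) the nucleation events,
#' boundary trajectories and coverage as CSV files.
#'
#' @param sim output of [simulate_kymograph()] (list `kymo`, `truth`) or a
#'   bare [kymograph].
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return the directory, invisibly.
#' @export
write_kymograph <- function(sim, dir, stem = "kymo") {
  kymo <- if (inherits(sim, "kymograph")) sim else sim$kymo
  truth <- if (inherits(sim, "kymograph")) NULL else sim$truth
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(unname(kymo$channels), file.path(dir, paste0(stem, ".tif")))
  meta <- list(channels = names(kymo$channels),
               frame_interval_s = kymo$frame_interval_s,
               pixel_size_nm = kymo$pixel_size_nm)
  if (!is.null(truth)) meta$params <- unclass(truth$params)
  jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    write_table(truth$nucleation_events,
                file.path(dir, paste0(stem, "_nucleation_events.csv")))
    write_table(truth$boundary_trajectories,
                file.path(dir, paste0(stem, "_boundaries.csv")))
    write_table(data.frame(frame = seq_along(truth$coverage_fraction) - 1L,
                           coverage_fraction = truth$coverage_fraction),
                file.path(dir, paste0(stem, "_coverage.csv")))
  }
  invisible(dir)
}

#' Read a kymograph bundle written by [write_kymograph()]
#' @param dir directory containing `<stem>.tif` and `<stem>.json`.
#' @param stem file-name stem.
#' @return a [kymograph].
#' @export
read_kymograph <- function(dir, stem = "kymo") {
  meta <- jsonlite::read_json(file.path(dir, paste0(stem, ".json")),
                              simplifyVector = TRUE)
  img <- read_image(file.path(dir, paste0(stem, ".tif")))
  pages <- if (is.matrix(img$data)) list(img$data) else img$data
  names(pages) <- meta$channels
  kymograph(pages, frame_interval_s = meta$frame_interval_s,
            pixel_size_nm = meta$pixel_size_nm)
}
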