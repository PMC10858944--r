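# Readers and writers: TIFF stacks with JSON sidecar metadata, PSF grids
# as per-position TIFF directories with a CSV index, and YAML run
# configuration.

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 8-bit integer (native sensor depth) or 32-bit float
#' TIFF pages.  Float data are affinely mapped into `[0, 1]` for storage;
#' the offset and scale are recorded in the JSON sidecar together with the
#' pixel pitch and frame rate, so [read_stack()] restores the original
#' values.
#'
#' @param frames matrix or 3-D array `(time, y, x)`.
#' @param path output `.tif` path; the sidecar goes to `<path>.json`.
#' @param bit_depth 8 (integer counts in `[0, 255]`) or 32 (float).
#' @param pixel_pitch,frame_rate metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path, bit_depth = 32, pixel_pitch = NA,
                        frame_rate = NA) {
  if (is.matrix(frames)) frames <- array(frames, c(1, dim(frames)))
  nt <- dim(frames)[1]
  if (bit_depth == 8) {
    lo <- 0; sc <- 255
    pages <- lapply(seq_len(nt), function(f)
      matrix(frames[f, , ] / 255, dim(frames)[2], dim(frames)[3]))
    tiff::writeTIFF(pages, path, bits.per.sample = 8)
  } else {
    lo <- min(frames); hi <- max(frames)
    sc <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(nt), function(f)
      matrix((frames[f, , ] - lo) / sc, dim(frames)[2], dim(frames)[3]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
  }
  meta <- list(bit_depth = bit_depth, offset = lo, scale = sc,
               n_frames = nt, pixel_pitch = pixel_pitch,
               frame_rate = frame_rate)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' Plain multi-page TIFFs without a sidecar are accepted: values are
#' returned as stored (scaled to `[0, 1]` by the TIFF reader) and default
#' metadata is assumed with a prominent warning.
#'
#' @param path `.tif` path.
#' @return 3-D array `(time, y, x)` with attributes `pixel_pitch` and
#'   `frame_rate`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  } else {
    warning("no metadata sidecar for ", path,
            ": assuming offset 0, scale 1, pitch/frame rate unknown")
    meta <- list(offset = 0, scale = 1, bit_depth = 32,
                 pixel_pitch = NA, frame_rate = NA)
  }
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages)) {
    pg <- pages[[f]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    arr[f, , ] <- if (meta$bit_depth == 8) pg * 255 else pg * meta$scale + meta$offset
  }
  attr(arr, "pixel_pitch") <- meta$pixel_pitch
  attr(arr, "frame_rate") <- meta$frame_rate
  arr
}

#' Save a PSF grid as a TIFF directory with CSV index
#'
#' One 32-bit float TIFF per (depth, row, col) PSF, an `index.csv` naming
#' them, and a `meta.json` with the grid geometry.
#'
#' @param grid a `psf_grid`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_psf_grid <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(grid$psfs)
  idx <- expand.grid(depth_i = seq_len(d[1]), row = seq_len(d[2]),
                     col = seq_len(d[3]))
  idx$file <- sprintf("psf_d%02d_r%02d_c%02d.tif",
                      idx$depth_i, idx$row, idx$col)
  idx$depth_mm <- grid$depths[idx$depth_i]
  for (k in seq_len(nrow(idx))) {
    p <- matrix(grid$psfs[idx$depth_i[k], idx$row[k], idx$col[k], , ],
                d[4], d[5])
    write_stack(p, file.path(dir, idx$file[k]), bit_depth = 32,
                pixel_pitch = grid$pixel_pitch)
  }
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(depths = grid$depths, grid_rows = grid$grid_rows,
         grid_cols = grid$grid_cols, pixel_pitch = grid$pixel_pitch,
         grid_spacing_mm = grid$grid_spacing_mm),
    file.path(dir, "meta.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Load a PSF grid saved by [save_psf_grid()]
#'
#' @param dir directory containing `index.csv`, `meta.json` and the PSF
#'   TIFFs.
#' @return a `psf_grid`.
#' @export
load_psf_grid <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "index.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  first <- read_stack(file.path(dir, idx$file[1]))
  ky <- dim(first)[2]; kx <- dim(first)[3]
  psfs <- array(0, c(length(meta$depths), length(meta$grid_rows),
                     length(meta$grid_cols), ky, kx))
  for (k in seq_len(nrow(idx))) {
    p <- read_stack(file.path(dir, idx$file[k]))
    psfs[idx$depth_i[k], idx$row[k], idx$col[k], , ] <- p[1, , ]
  }
  psf_grid(psfs, depths = meta$depths, grid_rows = meta$grid_rows,
           grid_cols = meta$grid_cols, pixel_pitch = meta$pixel_pitch,
           grid_spacing_mm = meta$grid_spacing_mm, normalize = FALSE)
}

#' Save a contour pattern or phase mask as TIFF + JSON sidecar
#'
#' Patterns are written as 8-bit binary images; masks as 32-bit heights in
#' nm (via the [write_stack()] scaling sidecar), with design metadata in
#' the sidecar.
#'
#' @param x a `contour_pattern` or `phase_mask`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
save_mask_design <- function(x, path) {
  if (inherits(x, "contour_pattern")) {
    write_stack(x$mask * 255, path, bit_depth = 8,
                pixel_pitch = x$pixel_pitch)
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    meta$kind <- "contour_pattern"; meta$pattern_width <- x$pattern_width
  } else if (inherits(x, "phase_mask")) {
    write_stack(x$heights, path, bit_depth = 32, pixel_pitch = x$pixel_pitch)
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    meta$kind <- "phase_mask"
    meta[c("height_step", "max_height", "design_wavelength",
           "mask_to_sensor_distance", "delta_n")] <-
      x[c("height_step", "max_height", "design_wavelength",
          "mask_to_sensor_distance", "delta_n")]
  } else stop("unsupported object", call. = FALSE)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
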