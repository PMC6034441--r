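# --- CRC32 (for PNG chunks) -------------------------------------------------

.crc32_table_env <- new.env(parent = emptyenv())

.crc32_table <- function() {
  if (!is.null(.crc32_table_env$tab)) return(.crc32_table_env$tab)
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(c, 1)) else bitwShiftR(c, 1)
    }
    tab[n + 1] <- c
  }
  .crc32_table_env$tab <- tab
  tab
}

.crc32 <- function(bytes) {
  tab <- .crc32_table()
  c <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    c <- bitwXor(tab[bitwAnd(bitwXor(c, b[i]), 255L) + 1L], bitwShiftR(c, 8))
  }
  bitwXor(c, -1L)
}

.u32_be <- function(x) {
  # unsigned 32-bit big-endian raw from (possibly negative) R integer
  as.raw(c(bitwAnd(bitwShiftR(x, 24), 255L), bitwAnd(bitwShiftR(x, 16), 255L),
           bitwAnd(bitwShiftR(x, 8), 255L), bitwAnd(x, 255L)))
}

.png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(.u32_be(length(data)), body, .u32_be(.crc32(body)))
}

# minimal 16-bit greyscale PNG writer (png::writePNG is 8-bit only)
.write_png16 <- function(m, path) {
  nr <- nrow(m); nc <- ncol(m)
  v <- as.integer(round(pmin(pmax(m, 0), 1) * 65535))
  hi <- as.raw(v %/% 256L); lo <- as.raw(v %% 256L)
  # scanlines: filter byte 0 + big-endian samples, row-major
  sl <- raw((2L * nc + 1L) * nr)
  rowlen <- 2L * nc + 1L
  for (r in seq_len(nr)) {
    off <- (r - 1L) * rowlen
    idx <- (seq_len(nc) - 1L) * nr + r        # row r across columns
    sl[off + 1L] <- as.raw(0)
    sl[off + 1L + 2L * seq_len(nc) - 1L] <- hi[idx]
    sl[off + 1L + 2L * seq_len(nc)] <- lo[idx]
  }
  idat <- memCompress(sl, "gzip")   # zlib stream, as PNG requires
  ihdr <- c(.u32_be(nc), .u32_be(nr), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           .png_chunk("IHDR", ihdr), .png_chunk("IDAT", idat),
           .png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

# --- generic raster I/O -----------------------------------------------------

.img_ext <- function(path) tolower(tools::file_ext(path))

#' Read a raster image
#'
#' Reads PNG (8/16-bit) or TIFF (including 32-bit float) into a numeric
#' matrix (or array, for multi-channel images). Intensities arrive on
#' the file's native \[0, 1\] scale.
#'
#' @param path image file.
#' @return numeric matrix/array.
#' @export
read_image <- function(path) {
  .assert(file.exists(path), "image not found: %s", path)
  ext <- .img_ext(path)
  out <- tryCatch(switch(ext,
                         png = png::readPNG(path),
                         tif = ,
                         tiff = tiff::readTIFF(path),
                         stop(sprintf("unsupported image format '%s' for %s",
                                      ext, path), call. = FALSE)),
                  error = function(e)
                    stop(sprintf("cannot read %s as an image: %s", path,
                                 conditionMessage(e)), call. = FALSE))
  out
}

#' Write a raster image
#'
#' PNG at 8 or 16 bit (greyscale for 16), or TIFF at 32-bit float.
#' Values are expected in \[0, 1\]; lossless round trip within the
#' target dtype's precision.
#'
#' @param path output file (extension selects the format).
#' @param raster numeric matrix or array in \[0, 1\].
#' @param bits bit depth: 8 or 16 for PNG; TIFF always writes float32.
#' @return the path, invisibly.
#' @export
write_image <- function(path, raster, bits = 8) {
  ext <- .img_ext(path)
  if (ext == "png") {
    if (bits == 16) {
      .assert(is.matrix(raster), "16-bit PNG output supports greyscale only")
      .write_png16(raster, path)
    } else {
      png::writePNG(raster, path)
    }
  } else if (ext %in% c("tif", "tiff")) {
    suppressWarnings(tiff::writeTIFF(raster, path, bits.per.sample = 32L,
                                     reduce = FALSE))
  } else {
    stop(sprintf("unsupported image format '%s' for %s", ext, path),
         call. = FALSE)
  }
  invisible(path)
}

# --- depth frames -----------------------------------------------------------

#' Write a depth frame (float TIFF or portable text array + JSON sidecar)
#'
#' Depth in mm is stored either as 32-bit float TIFF (scaled by a factor
#' recorded in the sidecar, since TIFF sample values live in \[0, 1\])
#' or, for `.tsv` paths, as a plain tab-separated text matrix. The JSON
#' sidecar `<path>.json` carries units, scale, timestamp, ROI and pixel
#' pitch.
#'
#' @param path output file (`.tif`/`.tiff` or `.tsv`).
#' @param frame a [depth_frame()].
#' @param scale mm scale factor for TIFF storage.
#' @return the path, invisibly.
#' @export
write_depth_frame <- function(path, frame, scale = 10000) {
  .assert(inherits(frame, "depth_frame"), "frame must be a depth_frame")
  ext <- .img_ext(path)
  if (ext %in% c("tif", "tiff")) {
    write_image(path, frame$depth / scale)
  } else if (ext == "tsv") {
    utils::write.table(frame$depth, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    scale <- 1
  } else stop(sprintf("unsupported depth format '%s'", ext), call. = FALSE)
  sidecar <- list(units = "mm", scale = scale, timestamp = frame$timestamp,
                  roi = frame$roi, pixel_pitch = frame$pixel_pitch)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a depth frame written by [write_depth_frame()]
#'
#' @param path `.tif`/`.tiff` or `.tsv` file with `<path>.json` sidecar.
#' @return a [depth_frame()].
#' @export
read_depth_frame <- function(path) {
  side <- paste0(path, ".json")
  .assert(file.exists(side), "missing depth sidecar %s", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  ext <- .img_ext(path)
  depth <- if (ext %in% c("tif", "tiff")) {
    read_image(path) * meta$scale
  } else if (ext == "tsv") {
    as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  } else stop(sprintf("unsupported depth format '%s'", ext), call. = FALSE)
  dimnames(depth) <- NULL
  depth_frame(depth, roi = meta$roi, timestamp = meta$timestamp,
              pixel_pitch = meta$pixel_pitch)
}

# --- PS stack I/O -----------------------------------------------------------

#' Write a photometric-stereo stack with its light-geometry config
#'
#' One 16-bit PNG per light plus a YAML config listing each image path
#' with its (ps, qs) light coordinates — the format [read_ps_config()]
#' and the command-line interface consume.
#'
#' @param dir output directory.
#' @param stack an [image_stack()].
#' @param lights the matching [light_set()].
#' @return the config path, invisibly.
#' @export
write_ps_stack <- function(dir, stack, lights) {
  .assert(length(stack$images) == length(lights$ps),
          "stack and lights must match")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (i in seq_along(stack$images)) {
    fn <- sprintf("light_%02d.png", i)
    write_image(file.path(dir, fn), stack$images[[i]], bits = 16)
    entries[[i]] <- list(path = fn, ps = lights$ps[i], qs = lights$qs[i])
  }
  cfg <- list(pipeline = "ps", images = entries)
  if (!is.null(stack$pixel_pitch)) cfg$pixel_pitch <- stack$pixel_pitch
  cfgp <- file.path(dir, "ps_config.yaml")
  yaml::write_yaml(cfg, cfgp)
  invisible(cfgp)
}

#' Read a photometric-stereo stack config
#'
#' @param path YAML config written by [write_ps_stack()] (validated via
#'   [validate_config()]).
#' @return list with `stack` ([image_stack()]) and `lights`
#'   ([light_set()]).
#' @export
read_ps_config <- function(path) {
  cfg <- validate_config(path, pipeline = "ps")
  base <- dirname(path)
  imgs <- lapply(cfg$images, function(e) {
    p <- e$path
    if (!file.exists(p)) p <- file.path(base, e$path)
    as_luminance(read_image(p))
  })
  lights <- light_set(vapply(cfg$images, `[[`, 0, "ps"),
                      vapply(cfg$images, `[[`, 0, "qs"))
  list(stack = image_stack(imgs, pixel_pitch = cfg$pixel_pitch),
       lights = lights)
}
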