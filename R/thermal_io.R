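# Thermal frame data model and raster / table I/O.
#
# A frame is a 2-D grid of surface temperatures in degrees Celsius as
# exported by a radiometric LWIR camera (native FPA 320 x 240). All indices
# downstream are computed on Celsius values and are NOT unit-invariant:
# WSI = (T_S - T_W)/T_S changes under a shift to Kelvin or Fahrenheit, so
# temperatures must be Celsius throughout.

#' Construct a thermal frame
#'
#' Wraps a numeric matrix of temperatures (degrees Celsius, row-major,
#' top-left origin) together with acquisition metadata. Missing pixels are
#' represented by `NA`; all non-missing values must be finite.
#'
#' @param pixels numeric matrix of temperatures in degrees C. `NA`/`NaN`
#'   entries mark missing pixels.
#' @param meta optional metadata, see [frame_meta()].
#' @return An object of class `thermal_frame` with elements `pixels`,
#'   `height`, `width` and `meta`.
#' @export
thermal_frame <- function(pixels, meta = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (any(is.infinite(pixels)))
    stop("thermal frame contains non-finite (infinite) temperatures", call. = FALSE)
  pixels[is.nan(pixels)] <- NA_real_
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         meta = meta),
    class = "thermal_frame"
  )
}

#' Frame acquisition metadata
#'
#' @param species `"durum"` or `"common"`.
#' @param variety variety code (one of the 18 monitored codes, see
#'   [wheat_varieties()]).
#' @param stage phenological stage: `"stem_elongation"`, `"heading_begins"`,
#'   `"milky_waxy"` or `"full_ripening"`.
#' @param session measurement-session identifier.
#' @param replicate replicate (block) number.
#' @param frame_index frame number within the session.
#' @return A list of class `frame_meta`.
#' @export
frame_meta <- function(species = NA_character_, variety = NA_character_,
                       stage = NA_character_, session = NA_integer_,
                       replicate = NA_integer_, frame_index = NA_integer_) {
  if (!is.na(species))
    species <- match.arg(species, c("durum", "common"))
  if (!is.na(stage))
    stage <- match.arg(stage, stage_levels())
  structure(list(species = species, variety = variety, stage = stage,
                 session = session, replicate = replicate,
                 frame_index = frame_index),
            class = "frame_meta")
}

#' @export
print.thermal_frame <- function(x, ...) {
  nv <- n_valid_pixels(x)
  cat(sprintf("<thermal_frame> %d x %d px, %d valid", x$height, x$width, nv))
  if (nv > 0)
    cat(sprintf(", range %.2f..%.2f degC",
                min(x$pixels, na.rm = TRUE), max(x$pixels, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' Count valid (non-missing) pixels of a frame
#' @param frame a [thermal_frame()].
#' @return integer count.
#' @export
n_valid_pixels <- function(frame) sum(!is.na(frame$pixels))

#' Read a thermal frame from disk
#'
#' Supported formats: a headerless CSV matrix of Celsius values (missing
#' pixels as the literal token `NA`), or a single-band 32-bit-float TIFF
#' (missing pixels as `NaN`). Format is inferred from the file extension
#' unless given.
#'
#' @param path path to the raster file.
#' @param format `"auto"`, `"csv"` or `"tiff"`.
#' @param meta optional [frame_meta()] to attach.
#' @return A [thermal_frame()].
#' @export
read_frame <- function(path, format = c("auto", "csv", "tiff"), meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("frame file does not exist: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "csv"
  pixels <- switch(format,
    csv = read_frame_csv(path),
    tiff = read_frame_tiff(path)
  )
  thermal_frame(pixels, meta = meta)
}

read_frame_csv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    stop("empty frame file: ", path, call. = FALSE)
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1)
    stop("ragged CSV frame (rows of unequal length) in ", path, call. = FALSE)
  flat <- trimws(unlist(cells))
  vals <- suppressWarnings(as.numeric(flat))
  bad <- which(is.na(vals) & !(flat %in% c("NA", "nan", "NaN")))
  if (length(bad)) {
    i <- bad[1]
    stop(sprintf("non-numeric cell '%s' at row %d, column %d of %s",
                 flat[i], (i - 1) %/% ncols[1] + 1, (i - 1) %% ncols[1] + 1,
                 path), call. = FALSE)
  }
  matrix(vals, nrow = length(lines), ncol = ncols[1], byrow = TRUE)
}

read_frame_tiff <- function(path) {
  img <- tryCatch(tiff::readTIFF(path),
                  error = function(e) stop("unreadable TIFF ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] != 1)
      stop(sprintf("multi-band raster (%d bands) in %s; single band required",
                   dim(img)[3], path), call. = FALSE)
    img <- img[, , 1]
  }
  img
}

#' Write a thermal frame to disk
#'
#' CSV output is lossless (values serialised with 17 significant digits,
#' missing pixels as `NA`). TIFF output is a single-band 32-bit IEEE-float
#' strip with missing pixels stored as `NaN`; note float32 carries ~7
#' significant digits, ample for temperatures at the camera's ~60 mK NETD.
#'
#' @param frame a [thermal_frame()].
#' @param path output path.
#' @param format `"auto"`, `"csv"` or `"tiff"` (inferred from extension).
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path, format = c("auto", "csv", "tiff")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "csv"
  switch(format,
    csv = write_frame_csv(frame$pixels, path),
    tiff = write_float_tiff(frame$pixels, path)
  )
  invisible(path)
}

write_frame_csv <- function(m, path) {
  txt <- sprintf("%.17g", m)
  txt[is.na(m)] <- "NA"
  dim(txt) <- dim(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(txt, 1, paste, collapse = ","), con)
}

# Minimal single-strip grayscale 32-bit IEEE-float little-endian TIFF writer.
# The bundled tiff package clamps float data to [0, 1] on write, which cannot
# represent Celsius rasters; it reads float TIFFs losslessly, so only the
# writer is provided here. Missing pixels are stored as NaN.
write_float_tiff <- function(m, path) {
  h <- nrow(m); w <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  writeBin(charToRaw("II"), con)      # little-endian byte order
  wb(42, 2)                           # TIFF magic
  wb(8, 4)                            # offset of first IFD
  tags <- list(                       # tag id, type (3=SHORT, 4=LONG), count, value
    c(256, 3, 1, w),                  # ImageWidth
    c(257, 3, 1, h),                  # ImageLength
    c(258, 3, 1, 32),                 # BitsPerSample
    c(259, 3, 1, 1),                  # Compression: none
    c(262, 3, 1, 1),                  # Photometric: BlackIsZero
    c(273, 4, 1, 0),                  # StripOffsets, patched below
    c(277, 3, 1, 1),                  # SamplesPerPixel
    c(278, 4, 1, h),                  # RowsPerStrip: one strip
    c(279, 4, 1, 4 * h * w),          # StripByteCounts
    c(339, 3, 1, 3)                   # SampleFormat: IEEE float
  )
  n <- length(tags)
  tags[[6]][4] <- 8 + 2 + n * 12 + 4  # pixel data follows the IFD
  wb(n, 2)
  for (t in tags) {
    wb(t[1], 2); wb(t[2], 2); wb(t[3], 4)
    if (t[2] == 3) { wb(t[4], 2); wb(0, 2) } else wb(t[4], 4)
  }
  wb(0, 4)                            # no further IFD
  px <- as.numeric(t(m))              # row-major strip
  px[is.na(px)] <- NaN
  writeBin(px, con, size = 4, endian = "little")
}

#' Read a study manifest
#'
#' The manifest is a single study-level CSV pairing every frame file with its
#' acquisition metadata, one row per frame, with columns
#' `file,species,variety,stage,session,replicate,frame_index`.
#'
#' @param path manifest CSV path.
#' @return A data.frame with validated `species` and `stage` columns.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("file", "species", "variety", "stage", "session",
                "replicate", "frame_index")
  missing <- setdiff(required, names(man))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(man$species), c("durum", "common"))
  if (length(bad))
    stop("unknown species in manifest: ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(man$stage), stage_levels())
  if (length(bad))
    stop("unknown phenological stage in manifest: ",
         paste(bad, collapse = ", "), call. = FALSE)
  man
}

#' Read a yield-component table
#'
#' Expects columns `variety,yield_t_ha,culms_m2,spikes_m2,biomass_t_ha`
#' (extra columns are kept). Adds an `is_modern` flag from the variety code:
#' the modern cultivars are PG and SV (durum) and AX and AL (common); all
#' other codes are landraces or their seeded mixtures.
#'
#' @param path CSV path.
#' @param species `"durum"` or `"common"`; used to validate variety codes.
#' @return A data.frame of class `yield_table`.
#' @export
read_yield_table <- function(path, species = c("durum", "common")) {
  species <- match.arg(species)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("variety", "yield_t_ha", "culms_m2", "spikes_m2",
                "biomass_t_ha")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("yield table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  known <- wheat_varieties(species)$variety
  bad <- setdiff(tab$variety, known)
  if (length(bad))
    stop("unknown ", species, " variety code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  num <- tab[required[-1]]
  if (any(vapply(num, function(x) any(!is.finite(x) | x < 0), logical(1))))
    stop("yield components must be finite and non-negative", call. = FALSE)
  tab$is_modern <- tab$variety %in% modern_varieties(species)
  tab$species <- species
  class(tab) <- c("yield_table", "data.frame")
  tab
}

#' Monitored wheat varieties
#'
#' The 9 durum and 9 common wheat entries of the field trial: three
#' landraces grown in purity, four seeded mixtures of the landraces, and two
#' modern cultivars per species.
#'
#' @param species `"durum"`, `"common"`, or both (default).
#' @return data.frame with columns `species`, `variety`, `is_modern`.
#' @export
wheat_varieties <- function(species = c("durum", "common")) {
  species <- match.arg(species, several.ok = TRUE)
  durum <- c("SC", "MZ", "SL", "MixD1", "MixD2", "MixD3", "MixD4", "PG", "SV")
  common <- c("RS", "RM", "GR", "MixC1", "MixC2", "MixC3", "MixC4", "AX", "AL")
  out <- rbind(
    data.frame(species = "durum", variety = durum,
               is_modern = durum %in% c("PG", "SV")),
    data.frame(species = "common", variety = common,
               is_modern = common %in% c("AX", "AL"))
  )
  out[out$species %in% species, , drop = FALSE]
}

modern_varieties <- function(species) {
  v <- wheat_varieties(species)
  v$variety[v$is_modern]
}
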