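# Readers and writers for slices, masks and manifests.
#
# DICOM support is a minimal single-frame reader/writer for uncompressed
# little-endian transfer syntaxes (explicit and implicit VR), sufficient
# for the grayscale axial slices this package consumes; compressed or
# multi-frame files are rejected with an informative error.

HU_WINDOW <- c(-1000, 400)  # standard lung/soft-tissue window

#' Read one CT slice
#'
#' Reads a DICOM file or an 8/16-bit grayscale PNG/TIFF image.  DICOM pixel
#' data are converted to Hounsfield units via the rescale slope/intercept,
#' windowed to \[-1000, 400\] HU and normalized to \[0, 1\]; PNG/TIFF values
#' are scaled by bit depth to \[0, 1\].
#'
#' @param path file path.
#' @return list with `image` (numeric matrix in \[0,1\]) and `meta`
#'   (source path, modality, rescale slope/intercept, pixel spacing, bit
#'   depth).
#' @export
read_slice <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  lower <- tolower(path)
  magic <- readBin(path, "raw", n = 132)
  is_dicom <- length(magic) == 132 &&
    identical(magic[129:132], charToRaw("DICM"))
  if (is_dicom || grepl("\\.dcm$", lower)) return(read_dicom_slice(path))
  if (grepl("\\.png$", lower)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    img <- tiff::readTIFF(path)
  } else stop("I/O error: unsupported file type: ", path, call. = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  list(image = img,
       meta = list(source = path, modality = "image", slope = 1, intercept = 0,
                   spacing = NULL, bits = NA_integer_))
}

#' Write / read a binary mask as 8-bit PNG
#'
#' Masks are stored with values 0 and 255; the round trip is bit-exact.
#' Reading a file with any other pixel value is an error.
#'
#' @param mask binary 0/1 matrix.
#' @param path file path (`.png`).
#' @return `write_mask` returns `path` invisibly; `read_mask` returns an
#'   integer 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_matrix(mask)
  png::writePNG(mask + 0, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (!all(img %in% c(0, 1)))
    stop("mask file contains non-binary pixel values: ", path, call. = FALSE)
  matrix(as.integer(img), nrow(img), ncol(img))
}

#' Write a grayscale slice image
#'
#' Writes 16-bit TIFF (default) or 8-bit PNG depending on the extension.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param path file path (`.tif`/`.tiff` or `.png`).
#' @return `path`, invisibly.
#' @export
write_slice <- function(img, path) {
  stopifnot_image(img)
  img <- pmin(pmax(img, 0), 1)
  if (grepl("\\.png$", tolower(path))) png::writePNG(img, path)
  else tiff::writeTIFF(img, path, bits.per.sample = 16)
  invisible(path)
}

#' Write a phantom dataset to disk
#'
#' Writes per-slice 16-bit TIFF images, 8-bit PNG ground-truth masks (lung
#' slices only) and the manifest as CSV and JSON.
#'
#' @param dataset result of [make_dataset()].
#' @param dir output directory (created if needed).
#' @return the manifest data frame (with file paths), invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$image_path <- file.path(dir, sprintf("slice_%04d.tif", man$id))
  man$mask_path <- ifelse(man$contains_lung,
                          file.path(dir, sprintf("mask_%04d.png", man$id)), NA)
  for (i in seq_len(nrow(man))) {
    write_slice(dataset$slices[[i]]$image, man$image_path[i])
    if (man$contains_lung[i]) write_mask(dataset$slices[[i]]$mask, man$mask_path[i])
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(man, file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(man)
}

# ---- minimal DICOM ---------------------------------------------------------

dicom_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# string value with trailing padding (space or nul) stripped
dicom_string <- function(raw, pos, len) {
  r <- raw[pos:(pos + len - 1L)]
  r <- r[r != as.raw(0)]
  sub("\\s+$", "", rawToChar(r))
}

read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || !identical(raw[129:132], charToRaw("DICM")))
    stop("I/O error: not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  pos <- 133L
  u16 <- function(p) readBin(raw[p:(p + 1)], "integer", size = 2, endian = "little",
                             signed = FALSE)
  u32 <- function(p) readBin(raw[p:(p + 3)], "integer", size = 4, endian = "little")
  tags <- list()
  explicit <- TRUE  # file meta is always explicit little endian
  transfer <- "1.2.840.10008.1.2.1"
  meta_end <- NA_integer_
  while (pos + 7 <= length(raw)) {
    if (!is.na(meta_end) && pos >= meta_end) {
      explicit <- transfer != "1.2.840.10008.1.2"
      meta_end <- NA_integer_
    }
    group <- u16(pos); elem <- u16(pos + 2L)
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% dicom_long_vrs) { len <- u32(pos + 8L); hdr <- 12L }
      else { len <- u16(pos + 6L); hdr <- 8L }
    } else { vr <- "UN"; len <- u32(pos + 4L); hdr <- 8L }
    if (len < 0) stop("I/O error: undefined-length DICOM element unsupported ",
                      "(compressed pixel data?): ", path, call. = FALSE)
    data_pos <- pos + hdr
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- list(pos = data_pos, len = len, vr = vr)
    if (group == 2L && elem == 0L)
      meta_end <- data_pos + len + u32(data_pos)
    if (group == 2L && elem == 16L)
      transfer <- dicom_string(raw, data_pos, len)
    pos <- data_pos + len
  }
  if (!transfer %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop("I/O error: unsupported (compressed?) transfer syntax ", transfer,
         ": ", path, call. = FALSE)
  get_str <- function(key, default = NULL) {
    t <- tags[[key]]
    if (is.null(t) || t$len == 0) return(default)
    dicom_string(raw, t$pos, t$len)
  }
  get_us <- function(key, default = NULL) {
    t <- tags[[key]]
    if (is.null(t)) return(default)
    u16(t$pos)
  }
  nframes <- get_str("0028,0008")
  if (!is.null(nframes) && as.integer(nframes) > 1)
    stop("I/O error: multi-frame DICOM unsupported (2D slices only): ", path,
         call. = FALSE)
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  bits <- get_us("0028,0100", 16L)
  pixrep <- get_us("0028,0103", 0L)
  slope <- as.numeric(get_str("0028,1053", "1"))
  intercept <- as.numeric(get_str("0028,1052", "0"))
  spacing_str <- get_str("0028,0030")
  spacing <- if (is.null(spacing_str)) NULL else
    as.numeric(strsplit(spacing_str, "\\\\")[[1]])
  pd <- tags[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(pd))
    stop("I/O error: DICOM file lacks image dimensions or pixel data: ", path,
         call. = FALSE)
  n <- rows * cols
  if (bits == 16) {
    px <- readBin(raw[pd$pos:(pd$pos + 2L * n - 1L)], "integer", n = n, size = 2,
                  endian = "little", signed = pixrep == 1L)
  } else if (bits == 8) {
    px <- as.integer(raw[pd$pos:(pd$pos + n - 1L)])
  } else stop("I/O error: unsupported bits allocated: ", bits, call. = FALSE)
  hu <- slope * px + intercept
  img <- (pmin(pmax(hu, HU_WINDOW[1]), HU_WINDOW[2]) - HU_WINDOW[1]) /
    (HU_WINDOW[2] - HU_WINDOW[1])
  # DICOM pixel data are row-major
  img <- matrix(img, nrow = cols, ncol = rows)
  img <- t(img)
  list(image = img,
       meta = list(source = path, modality = get_str("0008,0060", "CT"),
                   slope = slope, intercept = intercept, spacing = spacing,
                   bits = bits))
}

#' Write a minimal CT DICOM slice
#'
#' Writes an uncompressed explicit-VR little-endian single-frame secondary
#' capture with the standard rescale tags, mainly for round-trip testing
#' and interchange of phantom slices.
#'
#' @param pixels integer matrix of stored pixel values (unsigned 16-bit).
#' @param path output path.
#' @param slope,intercept rescale slope and intercept mapping stored values
#'   to Hounsfield units.
#' @param spacing length-2 pixel spacing in mm.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(pixels, path, slope = 1, intercept = -1024,
                        spacing = c(1, 1)) {
  stopifnot(is.matrix(pixels))
  px <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  if (any(px < 0 | px > 65535)) stop("stored pixel values must be in [0, 65535]",
                                     call. = FALSE)
  u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  pad <- function(s, nul = FALSE) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, if (nul) as.raw(0) else charToRaw(" "))
    r
  }
  el <- function(group, elem, vr, value) {
    tag <- c(u16raw(group), u16raw(elem))
    if (vr %in% dicom_long_vrs)
      c(tag, charToRaw(vr), as.raw(c(0, 0)), u32raw(length(value)), value)
    else c(tag, charToRaw(vr), u16raw(length(value)), value)
  }
  meta <- c(el(2L, 2L, "UI", pad("1.2.840.10008.5.1.4.1.1.7", TRUE)),
            el(2L, 3L, "UI", pad("1.2.826.0.1.3680043.9999.1", TRUE)),
            el(2L, 16L, "UI", pad("1.2.840.10008.1.2.1", TRUE)))
  meta <- c(el(2L, 0L, "UL", u32raw(length(meta))), meta)
  pdata <- writeBin(as.integer(as.vector(t(px))), raw(), size = 2, endian = "little")
  body <- c(el(8L, 0x60L, "CS", pad("CT")),
            el(0x28L, 2L, "US", u16raw(1L)),
            el(0x28L, 4L, "CS", pad("MONOCHROME2")),
            el(0x28L, 0x10L, "US", u16raw(nrow(px))),
            el(0x28L, 0x11L, "US", u16raw(ncol(px))),
            el(0x28L, 0x30L, "DS", pad(paste(spacing, collapse = "\\"))),
            el(0x28L, 0x100L, "US", u16raw(16L)),
            el(0x28L, 0x101L, "US", u16raw(16L)),
            el(0x28L, 0x102L, "US", u16raw(15L)),
            el(0x28L, 0x103L, "US", u16raw(0L)),
            el(0x28L, 0x1052L, "DS", pad(format(intercept))),
            el(0x28L, 0x1053L, "DS", pad(format(slope))),
            el(0x7fe0L, 0x10L, "OW", pdata))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
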