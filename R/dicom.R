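# Minimal DICOM support: uncompressed, little-endian, single-frame
# monochrome objects (explicit or implicit VR), which covers digital
# mammography secondary-capture exports. Pixel data are kept as raw
# integers; no window/level or rescale is ever applied.

.short_vrs <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS",
                "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM", "UI", "UL",
                "US")
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.read_u16 <- function(con) readBin(con, "integer", 1L, 2L, signed = FALSE,
                                   endian = "little")
.read_u32 <- function(con) readBin(con, "integer", 1L, 4L, endian = "little")

.tag_key <- function(group, elem) sprintf("%04X,%04X", group, elem)

.parse_element_value <- function(vr, bytes, little = TRUE) {
  if (vr %in% c("US")) {
    readBin(bytes, "integer", length(bytes) / 2L, 2L, signed = FALSE,
            endian = "little")
  } else if (vr %in% c("UL", "SL")) {
    readBin(bytes, "integer", length(bytes) / 4L, 4L, endian = "little")
  } else if (vr %in% c("OW", "OB")) {
    bytes
  } else {
    sub("[ \\0]+$", "", rawToChar(bytes))
  }
}

#' Read a DICOM file
#'
#' Parses uncompressed little-endian DICOM (explicit or implicit VR) with a
#' monochrome pixel array. Returns the raw integer pixel matrix (rows x
#' columns, exactly as stored — no windowing, no rescale) together with the
#' decoded header elements.
#'
#' @param path DICOM file path.
#' @return A list with `pixels` (integer matrix, rows x columns),
#'   `bits_stored`, `photometric`, and `header` (named list keyed by
#'   "GGGG,EEEE" tag strings).
#' @export
read_dicom <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", 132L)
  if (length(preamble) < 132L || rawToChar(preamble[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM magic): ", path)
  header <- list()
  explicit <- TRUE
  pixel_bytes <- NULL
  repeat {
    group <- .read_u16(con)
    if (length(group) == 0L) break
    elem <- .read_u16(con)
    if (explicit || group == 0x0002L) {
      vr <- rawToChar(readBin(con, "raw", 2L))
      if (vr %in% .long_vrs) {
        readBin(con, "raw", 2L)  # reserved
        len <- .read_u32(con)
      } else if (vr %in% .short_vrs) {
        len <- .read_u16(con)
      } else {
        stop(sprintf("unsupported or implicit VR '%s' at tag %s in %s", vr,
                     .tag_key(group, elem), path))
      }
    } else {
      vr <- "UN"
      len <- .read_u32(con)
    }
    if (len < 0L) stop("undefined-length elements are not supported: ", path)
    bytes <- readBin(con, "raw", len)
    key <- .tag_key(group, elem)
    if (group == 0x7FE0L && elem == 0x0010L) {
      pixel_bytes <- bytes
    } else {
      header[[key]] <- .parse_element_value(vr, bytes)
    }
    if (key == .tag_key(0x0002L, 0x0010L)) {
      ts <- header[[key]]
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (ts != "1.2.840.10008.1.2.1")
        stop("unsupported transfer syntax ", ts, " in ", path)
    }
  }
  if (is.null(pixel_bytes))
    stop("DICOM file has no PixelData (7FE0,0010): ", path)
  photometric <- header[["0028,0004"]]
  if (is.null(photometric)) photometric <- "MONOCHROME2"
  if (!photometric %in% c("MONOCHROME1", "MONOCHROME2"))
    stop("non-monochrome photometric interpretation '", photometric,
         "' in ", path)
  rows <- header[["0028,0010"]]
  cols <- header[["0028,0011"]]
  bits_alloc <- header[["0028,0100"]]
  if (is.null(rows) || is.null(cols) || is.null(bits_alloc))
    stop("missing Rows/Columns/BitsAllocated in ", path)
  vals <- if (bits_alloc <= 8L) {
    as.integer(pixel_bytes[seq_len(rows * cols)])
  } else {
    readBin(pixel_bytes, "integer", rows * cols, 2L, signed = FALSE,
            endian = "little")
  }
  bits_stored <- header[["0028,0101"]]
  if (is.null(bits_stored)) bits_stored <- bits_alloc
  # DICOM stores pixel data row by row
  pixels <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  list(pixels = pixels, bits_stored = as.integer(bits_stored),
       photometric = photometric, header = header)
}

.dicom_element <- function(group, elem, vr, value) {
  if (vr == "US") {
    data <- writeBin(as.integer(value), raw(), 2L, endian = "little")
  } else if (vr == "UL") {
    data <- writeBin(as.integer(value), raw(), 4L, endian = "little")
  } else if (vr %in% c("OW", "OB")) {
    data <- value
  } else {
    data <- charToRaw(as.character(value))
    if (length(data) %% 2L == 1L)
      data <- c(data, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  head <- c(writeBin(as.integer(group), raw(), 2L, endian = "little"),
            writeBin(as.integer(elem), raw(), 2L, endian = "little"),
            charToRaw(vr))
  if (vr %in% .long_vrs) {
    head <- c(head, as.raw(c(0L, 0L)),
              writeBin(length(data), raw(), 4L, endian = "little"))
  } else {
    head <- c(head, writeBin(length(data), raw(), 2L, endian = "little"))
  }
  c(head, data)
}

#' Write a minimal DICOM file (synthetic/secondary-capture use)
#'
#' Writes an explicit-VR little-endian monochrome DICOM object around an
#' integer pixel matrix. Intended for synthetic phantoms and test data, not
#' for clinical round-tripping of full headers.
#'
#' @param pixels integer matrix (rows x columns) of non-negative values.
#' @param path output path.
#' @param patient_id,patient_name,patient_age,view header fields; `view` is
#'   "CC" or "MLO".
#' @param pixel_spacing_mm optional pixel spacing written to (0028,0030).
#' @param bits_stored sample depth; values must fit in it.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(pixels, path, patient_id = "ANON",
                        patient_name = "ANON", patient_age = NULL,
                        view = NULL, pixel_spacing_mm = NULL,
                        bits_stored = 16L) {
  stopifnot(is.matrix(pixels), all(pixels >= 0),
            all(pixels < 2^bits_stored), all(pixels == round(pixels)))
  bits_alloc <- if (bits_stored <= 8L) 8L else 16L
  vals <- as.integer(t(pixels))  # row-major
  pixel_bytes <- if (bits_alloc == 8L) as.raw(vals)
                 else writeBin(vals, raw(), 2L, endian = "little")
  meta <- .dicom_element(0x0002L, 0x0010L, "UI", "1.2.840.10008.1.2.1")
  body <- c(
    .dicom_element(0x0008L, 0x0060L, "CS", "MG"),
    .dicom_element(0x0010L, 0x0010L, "PN", patient_name),
    .dicom_element(0x0010L, 0x0020L, "LO", patient_id))
  if (!is.null(patient_age))
    body <- c(body, .dicom_element(0x0010L, 0x1010L, "AS",
                                   sprintf("%03dY", as.integer(patient_age))))
  if (!is.null(view))
    body <- c(body, .dicom_element(0x0018L, 0x5101L, "CS", view))
  body <- c(body,
    .dicom_element(0x0028L, 0x0002L, "US", 1L),
    .dicom_element(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    .dicom_element(0x0028L, 0x0010L, "US", nrow(pixels)),
    .dicom_element(0x0028L, 0x0011L, "US", ncol(pixels)))
  if (!is.null(pixel_spacing_mm))
    body <- c(body, .dicom_element(0x0028L, 0x0030L, "DS",
                                   sprintf("%g\\%g", pixel_spacing_mm,
                                           pixel_spacing_mm)))
  body <- c(body,
    .dicom_element(0x0028L, 0x0100L, "US", bits_alloc),
    .dicom_element(0x0028L, 0x0101L, "US", as.integer(bits_stored)),
    .dicom_element(0x0028L, 0x0102L, "US", as.integer(bits_stored) - 1L),
    .dicom_element(0x0028L, 0x0103L, "US", 0L),
    .dicom_element(0x7FE0L, 0x0010L, "OW", pixel_bytes))
  grouplen <- .dicom_element(0x0002L, 0x0000L, "UL", length(meta))
  out <- c(raw(128L), charToRaw("DICM"), grouplen, meta, body)
  writeBin(out, path)
  invisible(path)
}

.extract_patient_record <- function(hdr, source_file) {
  age_raw <- hdr[["0010,1010"]]
  age <- if (is.null(age_raw)) NA_integer_
         else as.integer(sub("^0*([0-9]+)[DWMY]?$", "\\1", age_raw))
  pid <- hdr[["0010,0020"]]
  if (is.null(pid) || !nzchar(pid))
    stop("PatientID (0010,0020) missing or empty in ", source_file)
  known <- c("0010,0020", "0010,1010", "0018,5101")
  extra <- hdr[setdiff(names(hdr), known)]
  extra <- extra[!vapply(extra, is.raw, logical(1))]
  list(patient_id = pid, age = age,
       view = if (is.null(hdr[["0018,5101"]])) NA_character_
              else hdr[["0018,5101"]],
       source_file = source_file, extra = extra)
}

#' Convert DICOM mammograms to PNG with a metadata CSV
#'
#' For each input file: decode the pixel array, write it as a PNG with the
#' stored integer values preserved exactly (8-bit PNG for depths up to 8
#' bits, 16-bit PNG otherwise; no window/level applied), and append one
#' patient row (patient_id, age, view, source_file) to a cumulative CSV in
#' `out_dir`.
#'
#' @param dicom_paths character vector of DICOM file paths.
#' @param out_dir output directory (created if needed).
#' @param csv_name file name of the cumulative metadata CSV.
#' @return Invisibly, a list with `images` (list of [mammogram()]),
#'   `records` (metadata data.frame) and `png_paths`.
#' @export
dicom_to_png <- function(dicom_paths, out_dir, csv_name = "patients.csv") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(out_dir, csv_name)
  images <- list()
  png_paths <- character(0)
  rows <- list()
  for (p in dicom_paths) {
    dcm <- read_dicom(p)
    rec <- .extract_patient_record(dcm$header, basename(p))
    maxval <- 2^dcm$bits_stored - 1
    png_path <- file.path(out_dir,
                          paste0(tools::file_path_sans_ext(basename(p)),
                                 ".png"))
    if (dcm$bits_stored <= 8L) {
      png::writePNG(dcm$pixels / 255, target = png_path)
    } else {
      write_png_gray16(dcm$pixels, png_path)
    }
    spacing <- NULL
    sp <- dcm$header[["0028,0030"]]
    if (!is.null(sp)) spacing <- as.numeric(strsplit(sp, "\\\\")[[1]][1])
    view <- if (is.na(rec$view)) NULL else rec$view
    images[[length(images) + 1L]] <-
      mammogram(dcm$pixels / maxval, pixel_spacing_mm = spacing, view = view)
    png_paths <- c(png_paths, png_path)
    rows[[length(rows) + 1L]] <-
      data.frame(patient_id = rec$patient_id, age = rec$age,
                 view = rec$view, source_file = rec$source_file,
                 stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  if (file.exists(csv_path)) {
    old <- read.csv(csv_path, stringsAsFactors = FALSE)
    records <- rbind(old, records)
  }
  write.csv(records, csv_path, row.names = FALSE)
  invisible(list(images = images, records = records, png_paths = png_paths))
}
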