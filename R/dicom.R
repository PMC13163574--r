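#' Read a multi-frame cine file into a cine sequence
#'
#' Two dialects are supported: `"dicom"` — a multi-frame grayscale DICOM
#' (explicit or implicit VR little endian) with the frame timing taken from
#' FrameTime/CineRate, pixel spacing from PixelSpacing, and the ECG from the
#' waveform sequence when present; and `"image_stack"` — a directory of
#' numbered PNG frames with a `meta.json` sidecar (frame rate, spacing,
#' modality) and an optional `ecg.csv` sidecar (columns `time`, `amplitude`).
#' Pixel data deeper than 8 bits is linearly rescaled to 0-255 at read time.
#'
#' @param path file (dicom) or directory (image_stack) path.
#' @param dialect `"auto"` (directory implies image_stack), `"dicom"` or
#'   `"image_stack"`.
#' @param frame_rate override used when the file carries no frame timing.
#' @return A [cine_sequence()]; when no ECG element is found the sequence's
#'   `ecg` is absent and a warning is raised.
#' @export
read_cine <- function(path, dialect = c("auto", "dicom", "image_stack"),
                      frame_rate = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (dir.exists(path)) "image_stack" else "dicom"
  }
  if (dialect == "dicom") {
    read_cine_dicom(path, frame_rate)
  } else {
    read_cine_stack(path, frame_rate)
  }
}

#' Write a cine sequence as a re-readable fixture
#'
#' The written file round-trips through [read_cine()]: frame intensities are
#' preserved exactly; frame rate and ECG samples are preserved exactly by
#' the image-stack dialect and to numerical precision of their decimal /
#' 16-bit waveform encoding by the DICOM dialect.
#'
#' @param seq a [cine_sequence()].
#' @param path output file (dicom) or directory (image_stack).
#' @param dialect `"dicom"` or `"image_stack"`.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(seq, path, dialect = c("dicom", "image_stack")) {
  stopifnot(inherits(seq, "cine_sequence"))
  dialect <- match.arg(dialect)
  if (dialect == "dicom") write_cine_dicom(seq, path) else
    write_cine_stack(seq, path)
  invisible(path)
}

# ---- image-stack dialect ---------------------------------------------------

read_cine_stack <- function(path, frame_rate = NULL) {
  if (!dir.exists(path)) stop(sprintf("no such directory: %s", path),
                              call. = FALSE)
  files <- sort(list.files(path, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) < 2L) {
    stop(sprintf("image stack %s holds %d frame file(s); need >= 2",
                 path, length(files)), call. = FALSE)
  }
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  })
  meta_file <- file.path(path, "meta.json")
  meta <- if (file.exists(meta_file)) {
    jsonlite::read_json(meta_file, simplifyVector = TRUE)
  } else list()
  fr <- meta$frame_rate %||% frame_rate
  if (is.null(fr)) {
    stop("image stack carries no frame rate and no override was given",
         call. = FALSE)
  }
  ecg_file <- file.path(path, "ecg.csv")
  ecg <- NULL
  if (file.exists(ecg_file)) {
    tab <- utils::read.csv(ecg_file)
    dt <- diff(tab$time)
    ecg <- ecg_trace(tab$amplitude, sample_rate = 1 / stats::median(dt),
                     offset = tab$time[1])
  } else {
    warning("no ECG sidecar found: sequence has no ECG", call. = FALSE)
  }
  cine_sequence(frames, fr,
                pixel_spacing = unlist(meta$pixel_spacing) %||% NULL,
                ecg = ecg,
                source_modality = meta$source_modality %||% "SYNTH")
}

write_cine_stack <- function(seq, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(seq$frames)) {
    png::writePNG(seq$frames[[i]] / 255,
                  file.path(path, sprintf("frame_%04d.png", i)))
  }
  meta <- list(frame_rate = seq$frame_rate,
               source_modality = seq$source_modality)
  if (!is.null(seq$pixel_spacing)) meta$pixel_spacing <- seq$pixel_spacing
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(seq$ecg)) {
    e <- seq$ecg
    utils::write.csv(
      data.frame(time = e$offset + (seq_along(e$samples) - 1) / e$sample_rate,
                 amplitude = e$samples),
      file.path(path, "ecg.csv"), row.names = FALSE)
  }
  path
}

# ---- minimal DICOM codec ---------------------------------------------------
# Explicit/implicit VR little endian, flat tags plus defined/undefined-length
# sequences; covers multi-frame grayscale pixel data, cine timing, pixel
# spacing and the waveform (ECG) sequence.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
LONG_VRS <- c("OB", "OW", "OF", "OD", "SQ", "UT", "UN")

raw_uint <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                       endian = "little")

pad_even <- function(r, pad = as.raw(0)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

dcm_element <- function(group, elem, vr, value) {
  value <- pad_even(value, if (vr %in% c("UI", "OB")) as.raw(0) else
    charToRaw(" "))
  head <- c(raw_uint(group, 2), raw_uint(elem, 2), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, as.raw(c(0, 0)), raw_uint(length(value), 4), value)
  } else {
    c(head, raw_uint(length(value), 2), value)
  }
}

dcm_str <- function(group, elem, vr, s) {
  dcm_element(group, elem, vr, charToRaw(as.character(s)))
}

dcm_us <- function(group, elem, x) dcm_element(group, elem, "US",
                                               raw_uint(x, 2))
dcm_ul <- function(group, elem, x) dcm_element(group, elem, "UL",
                                               raw_uint(x, 4))
dcm_ds <- function(group, elem, x) {
  dcm_str(group, elem, "DS", paste(sprintf("%.16g", x), collapse = "\\"))
}

new_uid <- function() {
  paste0("1.2.826.0.1.3680043.9.7433.",
         paste(sample.int(9e6, 2), collapse = "."))
}

write_cine_dicom <- function(seq, path) {
  H <- nrow(seq$frames[[1]]); W <- ncol(seq$frames[[1]])
  sop_class <- "1.2.840.10008.5.1.4.1.1.7.2"   # multi-frame grayscale byte SC
  sop_inst <- new_uid()
  modality <- switch(seq$source_modality,
                     ICE = , TEE = , TTE = "US", MRI = "MR", ANGIO = "XA",
                     "OT")
  # pixel data: DICOM is row-major within each frame
  pix <- unlist(lapply(seq$frames, function(f) as.integer(t(f))),
                use.names = FALSE)
  body <- c(
    dcm_str(0x0008, 0x0016, "UI", sop_class),
    dcm_str(0x0008, 0x0018, "UI", sop_inst),
    dcm_str(0x0008, 0x0060, "CS", modality),
    dcm_str(0x0018, 0x0040, "IS", as.character(round(seq$frame_rate))),
    dcm_ds(0x0018, 0x1063, 1000 / seq$frame_rate),
    dcm_us(0x0028, 0x0002, 1),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_str(0x0028, 0x0008, "IS", as.character(length(seq$frames))),
    dcm_us(0x0028, 0x0010, H),
    dcm_us(0x0028, 0x0011, W),
    if (!is.null(seq$pixel_spacing)) dcm_ds(0x0028, 0x0030, seq$pixel_spacing),
    dcm_us(0x0028, 0x0100, 8),
    dcm_us(0x0028, 0x0101, 8),
    dcm_us(0x0028, 0x0102, 7),
    dcm_us(0x0028, 0x0103, 0),
    if (!is.null(seq$ecg)) dcm_waveform_sq(seq$ecg),
    dcm_element(0x7FE0, 0x0010, "OB", as.raw(pix))
  )
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_str(0x0002, 0x0002, "UI", sop_class),
    dcm_str(0x0002, 0x0003, "UI", sop_inst),
    dcm_str(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dcm_str(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9.7433.1")
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", raw_uint(length(meta_body), 4)),
            meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  path
}

# waveform sequence: one multiplex group item with a single ECG channel,
# 16-bit signed samples plus a decimal sensitivity for amplitude recovery
dcm_waveform_sq <- function(ecg) {
  max_abs <- max(abs(ecg$samples), .Machine$double.eps)
  sens <- max_abs / 32767
  q <- as.integer(round(ecg$samples / sens))
  item_body <- c(
    dcm_str(0x0018, 0x1068, "DS", sprintf("%.16g", ecg$offset * 1000)),
    dcm_us(0x003A, 0x0005, 1),
    dcm_ul(0x003A, 0x0010, length(q)),
    dcm_ds(0x003A, 0x001A, ecg$sample_rate),
    dcm_ds(0x003A, 0x0210, sens),
    dcm_us(0x5400, 0x1004, 16),
    dcm_str(0x5400, 0x1006, "CS", "SS"),
    dcm_element(0x5400, 0x1010, "OW",
                writeBin(q, raw(), size = 2, endian = "little"))
  )
  item <- c(raw_uint(0xFFFE, 2), raw_uint(0xE000, 2),
            raw_uint(length(item_body), 4), item_body)
  head <- c(raw_uint(0x5400, 2), raw_uint(0x0100, 2), charToRaw("SQ"),
            as.raw(c(0, 0)), raw_uint(length(item), 4))
  c(head, item)
}

# small implicit-VR dictionary for the tags this reader understands
IMPLICIT_VR <- c(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0060" = "CS",
  "0018,0040" = "IS", "0018,1063" = "DS", "0018,1068" = "DS",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0008" = "IS",
  "0028,0010" = "US", "0028,0011" = "US", "0028,0030" = "DS",
  "0028,0100" = "US", "0028,0101" = "US", "0028,0102" = "US",
  "0028,0103" = "US",
  "003A,0005" = "US", "003A,0010" = "UL", "003A,001A" = "DS",
  "003A,0210" = "DS",
  "5400,0100" = "SQ", "5400,1004" = "US", "5400,1006" = "CS",
  "5400,1010" = "OW", "7FE0,0010" = "OW"
)

tag_key <- function(group, elem) sprintf("%04X,%04X", group, elem)

read_u16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}
read_u32 <- function(raw, at) {
  as.integer(raw[at]) + 256 * as.integer(raw[at + 1L]) +
    65536 * as.integer(raw[at + 2L]) + 16777216 * as.integer(raw[at + 3L])
}

# parse a run of data elements from `bytes[at..end]`; returns a named list
# of raw values (SQ values are lists of parsed items)
parse_elements <- function(bytes, at, end, explicit, stop_group = NULL) {
  out <- list()
  while (at <= end - 7L) {
    group <- read_u16(bytes, at); elem <- read_u16(bytes, at + 2L)
    if (!is.null(stop_group) && group != stop_group) break
    key <- tag_key(group, elem)
    if (explicit) {
      vr <- rawToChar(bytes[(at + 4L):(at + 5L)])
      if (vr %in% LONG_VRS) {
        len <- read_u32(bytes, at + 8L); hdr <- 12L
      } else {
        len <- read_u16(bytes, at + 6L); hdr <- 8L
      }
    } else {
      vr <- unname(IMPLICIT_VR[key])
      if (is.na(vr)) vr <- "UN"
      len <- read_u32(bytes, at + 4L); hdr <- 8L
    }
    start <- at + hdr
    if (vr == "SQ") {
      sq_end <- if (len == 0xFFFFFFFF || len < 0) end else start + len - 1L
      res <- parse_items(bytes, start, sq_end, explicit)
      out[[key]] <- res$items
      at <- res$at
    } else {
      if (len > 0 && (start + len - 1L) > end) {
        stop(sprintf("corrupt DICOM element %s: declared length %d overruns file",
                     key, len), call. = FALSE)
      }
      out[[key]] <- if (len > 0) bytes[start:(start + len - 1L)] else raw(0)
      attr(out[[key]], "vr") <- vr
      at <- start + len
    }
  }
  list(values = out, at = at)
}

parse_items <- function(bytes, at, end, explicit) {
  items <- list()
  while (at <= end - 7L) {
    group <- read_u16(bytes, at); elem <- read_u16(bytes, at + 2L)
    len <- read_u32(bytes, at + 4L)
    at <- at + 8L
    if (group == 0xFFFE && elem == 0xE0DD) break      # sequence delimiter
    if (group != 0xFFFE || elem != 0xE000) {
      stop(sprintf("corrupt DICOM sequence: expected item tag at offset %d", at - 8L),
           call. = FALSE)
    }
    item_end <- if (len == 0xFFFFFFFF || len < 0) end else at + len - 1L
    res <- parse_elements(bytes, at, item_end, explicit)
    items[[length(items) + 1L]] <- res$values
    at <- if (len == 0xFFFFFFFF || len < 0) res$at + 8L else item_end + 1L
  }
  list(items = items, at = at)
}

dcm_string_value <- function(v) {
  if (is.null(v)) return(NULL)
  trimws(rawToChar(v[v != as.raw(0)]))
}

dcm_numeric_value <- function(v) {
  s <- dcm_string_value(v)
  if (is.null(s) || s == "") return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us_value <- function(v) if (is.null(v)) NULL else read_u16(v, 1L)

read_cine_dicom <- function(path, frame_rate = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  at <- 1L
  if (length(bytes) > 132L && rawToChar(bytes[129:132]) == "DICM") {
    meta <- parse_elements(bytes, 133L, length(bytes), explicit = TRUE,
                           stop_group = 0x0002)
    ts <- dcm_string_value(meta$values[["0002,0010"]]) %||% UID_EXPLICIT_LE
    at <- meta$at
  } else {
    ts <- UID_IMPLICIT_LE   # headerless stream: assume implicit LE
  }
  explicit <- !identical(ts, UID_IMPLICIT_LE)
  if (!ts %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE)) {
    stop(sprintf("unsupported transfer syntax %s (element 0002,0010)", ts),
         call. = FALSE)
  }
  ds <- parse_elements(bytes, at, length(bytes), explicit)$values
  rows <- dcm_us_value(ds[["0028,0010"]])
  cols <- dcm_us_value(ds[["0028,0011"]])
  if (is.null(rows) || is.null(cols)) {
    stop("missing Rows/Columns (elements 0028,0010 / 0028,0011)",
         call. = FALSE)
  }
  n_fr <- as.integer(dcm_numeric_value(ds[["0028,0008"]]) %||% 1)
  bits <- dcm_us_value(ds[["0028,0101"]]) %||% 8L
  pix <- ds[["7FE0,0010"]]
  if (is.null(pix)) stop("missing PixelData (element 7FE0,0010)",
                         call. = FALSE)
  per_frame <- rows * cols
  vals <- if (bits <= 8L) {
    as.integer(pix)
  } else {
    v <- readBin(pix, "integer", n = length(pix) / 2L, size = 2L,
                 signed = FALSE, endian = "little")
    as.integer(round(v * 255 / (2^bits - 1)))
  }
  if (length(vals) < per_frame * n_fr) {
    stop(sprintf("PixelData holds %d values, expected %d (element 7FE0,0010)",
                 length(vals), per_frame * n_fr), call. = FALSE)
  }
  frames <- lapply(seq_len(n_fr), function(k) {
    matrix(vals[((k - 1) * per_frame + 1):(k * per_frame)],
           nrow = rows, ncol = cols, byrow = TRUE)
  })
  ft <- dcm_numeric_value(ds[["0018,1063"]])
  cr <- dcm_numeric_value(ds[["0018,0040"]])
  fr <- if (!is.null(ft) && ft > 0) 1000 / ft else
    if (!is.null(cr) && cr > 0) cr else frame_rate
  if (is.null(fr)) {
    stop("file carries no frame rate (elements 0018,1063 / 0018,0040) and no override was given",
         call. = FALSE)
  }
  spacing <- dcm_numeric_value(ds[["0028,0030"]])
  ecg <- NULL
  wf <- ds[["5400,0100"]]
  if (!is.null(wf) && length(wf) >= 1L) {
    it <- wf[[1]]
    q <- readBin(it[["5400,1010"]], "integer",
                 n = length(it[["5400,1010"]]) / 2L, size = 2L,
                 signed = TRUE, endian = "little")
    sens <- dcm_numeric_value(it[["003A,0210"]]) %||% 1
    srate <- dcm_numeric_value(it[["003A,001A"]])
    off <- (dcm_numeric_value(it[["0018,1068"]]) %||% 0) / 1000
    ecg <- ecg_trace(q * sens, sample_rate = srate, offset = off)
  } else {
    warning("no waveform element found: sequence has no ECG", call. = FALSE)
  }
  modality <- dcm_string_value(ds[["0008,0060"]]) %||% "OT"
  src <- switch(modality, US = "ICE", MR = "MRI", XA = "ANGIO", "SYNTH")
  cine_sequence(frames, fr, pixel_spacing = spacing, ecg = ecg,
                source_modality = src)
}
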