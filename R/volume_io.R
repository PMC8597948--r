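#' Read a 3D volume from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`"tiff-stack"`}{one multi-page TIFF, pages along the third axis,
#'     with a mandatory JSON sidecar `<path>.json` holding at least
#'     `spacing_um` and optionally `axis_order`, `origin_um`, `space`,
#'     `intensity_offset` (used to restore signed integers stored as
#'     unsigned 16-bit).}
#'   \item{`"nrrd"`}{NRRD with `spacings` in the header (`raw` or `ascii`
#'     encoding, little-endian).}
#' }
#' Voxel spacing must be present in the file metadata or sidecar; there is no
#' silent 1 um default.
#'
#' @param path file path.
#' @param format `"tiff-stack"` or `"nrrd"`; default guesses from the
#'   extension.
#' @return a [volume3d()].
#' @export
read_volume <- function(path, format = c("auto", "tiff-stack", "nrrd")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "tiff-stack"
  if (format == "nrrd") read_nrrd(path) else read_tiff_stack(path)
}

#' Write a 3D volume to disk
#'
#' The TIFF writer stores integer-valued data losslessly as unsigned 16-bit
#' (an offset recorded in the sidecar restores the original values);
#' non-integer data are an error for TIFF — use NRRD, which stores the native
#' numeric type (`int16`, `int32`, `float`, `double`).
#'
#' @param vol a [volume3d()].
#' @param path output path.
#' @param format `"tiff-stack"` or `"nrrd"` (default from extension).
#' @param encoding NRRD payload encoding, `"raw"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "tiff-stack", "nrrd"),
                         encoding = "raw") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "tiff-stack"
  if (format == "nrrd") write_nrrd(vol, path, encoding) else write_tiff_stack(vol, path)
  invisible(path)
}

read_tiff_stack <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("TIFF stack ", path, " has no JSON sidecar with spacing_um; ",
         "refusing to assume a voxel size")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$spacing_um))
    stop("sidecar ", side, " lacks spacing_um")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  off <- if (is.null(meta$intensity_offset)) 0 else meta$intensity_offset
  arr <- arr - off
  if (isTRUE(meta$integer)) storage.mode(arr) <- "integer"
  volume3d(arr, meta$spacing_um,
           axis_order = meta$axis_order %||% c("ML", "DV", "AP"),
           origin_um = meta$origin_um %||% c(0, 0, 0),
           space = meta$space %||% "subject")
}

write_tiff_stack <- function(vol, path) {
  x <- vol$data
  if (max(abs(x - round(x))) > 0)
    stop("TIFF stack writer is integer-only; use NRRD for float volumes")
  lo <- min(x)
  if (max(x) - lo > 65535) stop("integer range exceeds 16 bits")
  off <- -lo
  pages <- lapply(seq_len(dim(x)[3]),
                  function(k) (x[, , k] + off) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(spacing_um = vol$spacing, axis_order = vol$axis_order,
               origin_um = vol$origin, space = vol$space,
               intensity_offset = off, integer = TRUE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

nrrd_types <- c("int16" = "short", "int32" = "int", "uint8" = "uchar",
                "float" = "float", "double" = "double")

read_nrrd <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  nl <- which(bytes == as.raw(10L))
  sep <- NULL  # header/payload separator: first blank line
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L || (p == prev + 2L && bytes[prev + 1L] == as.raw(13L))) {
      sep <- p; break
    }
    prev <- p
  }
  if (is.null(sep)) stop(path, ": no header/payload separator found")
  hdr_txt <- rawToChar(bytes[seq_len(sep)])
  lines <- strsplit(hdr_txt, "\r?\n")[[1]]
  if (!grepl("^NRRD", lines[1])) stop(path, " is not a NRRD file")
  fields <- list(); keys <- list()
  for (ln in lines[-1]) {
    if (ln == "" || grepl("^#", ln)) next
    if (grepl(":=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, ":=", fixed = TRUE)[[1]]
      keys[[trimws(kv[1])]] <- trimws(kv[2])
    } else {
      kv <- regmatches(ln, regexpr(": ", ln), invert = TRUE)[[1]]
      fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
    }
  }
  payload <- bytes[seq.int(sep + 1L, length(bytes))]
  need <- function(f) {
    if (is.null(fields[[f]])) stop("NRRD header lacks required field '", f, "'")
    fields[[f]]
  }
  if (as.integer(need("dimension")) != 3L) stop("only 3D NRRD supported")
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  if (is.null(fields$spacings))
    stop("NRRD header has no spacings; refusing to assume a voxel size")
  spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  type <- need("type")
  type <- names(nrrd_types)[match(type, nrrd_types)] %||% type
  enc <- tolower(need("encoding"))
  n <- prod(sizes)
  if (enc == "raw") {
    sz <- switch(type, int16 = 2L, int32 = 4L, uint8 = 1L, float = 4L, double = 8L)
    x <- readBin(payload, what = switch(type, int16 = , int32 = , uint8 = "integer",
                                        "double"),
                 n = n, size = sz, signed = type != "uint8",
                 endian = fields$endian %||% "little")
  } else if (enc %in% c("ascii", "txt", "text")) {
    x <- as.numeric(strsplit(trimws(rawToChar(payload)), "\\s+")[[1]])
    if (type %in% c("int16", "int32", "uint8")) x <- as.integer(round(x))
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(x) != n) stop("NRRD payload truncated")
  arr <- array(x, sizes)
  origin <- if (!is.null(fields[["axis mins"]]))
    as.numeric(strsplit(fields[["axis mins"]], "\\s+")[[1]]) else c(0, 0, 0)
  ax <- if (!is.null(keys[["probeloc_axis_order"]]))
    strsplit(keys[["probeloc_axis_order"]], "\\s+")[[1]] else c("ML", "DV", "AP")
  volume3d(arr, spacing, axis_order = ax, origin_um = origin,
           space = keys[["probeloc_space"]] %||% "subject")
}

write_nrrd <- function(vol, path, encoding = "raw") {
  x <- vol$data
  type <- if (is.integer(x)) {
    if (min(x) >= -32768 && max(x) <= 32767) "int16" else "int32"
  } else "double"
  hdr <- c("NRRD0004",
           paste0("type: ", nrrd_types[[type]]),
           "dimension: 3",
           paste0("sizes: ", paste(dim(x), collapse = " ")),
           paste0("spacings: ", paste(format(vol$spacing, digits = 15), collapse = " ")),
           paste0("axis mins: ", paste(format(vol$origin, digits = 15), collapse = " ")),
           paste0("encoding: ", encoding),
           "endian: little",
           paste0("probeloc_axis_order:=", paste(vol$axis_order, collapse = " ")),
           paste0("probeloc_space:=", vol$space),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (encoding == "raw") {
    writeBin(as.vector(x), con,
             size = switch(type, int16 = 2L, int32 = 4L, double = 8L),
             endian = "little")
  } else {
    writeChar(paste(format(as.vector(x), digits = 17), collapse = " "), con,
              eos = NULL)
  }
  invisible(path)
}

#' Read a region table CSV (`label,acronym,name`)
#'
#' @param path CSV path.
#' @return data.frame with integer `label`, character `acronym`, `name`.
#' @export
read_region_table <- function(path) {
  rt <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "acronym", "name") %in% names(rt)))
    stop("region table needs columns label, acronym, name")
  rt$label <- as.integer(rt$label)
  rt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
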