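## Surface overlay I/O: FreeSurfer MGH/MGZ (binary, big-endian, float32),
## GIFTI (XML, ASCII-encoded data arrays), and dense TSV. Only the features
## needed for per-vertex scalar overlays are implemented: single-volume
## files of shape vertices x frames.

MGH_HEADER_BYTES <- 284L
MGH_TYPE_FLOAT <- 3L

overlay_format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         mgh = "mgh", mgz = "mgh",
         gii = "gifti",
         tsv = "tsv", txt = "tsv",
         stop_densim(sprintf("cannot guess overlay format of '%s'", path),
                     "densim_format_error"))
}

mgh_connection <- function(path, mode) {
  if (grepl("\\.mgz$", path, ignore.case = TRUE)) {
    gzfile(path, mode)
  } else {
    file(path, mode)
  }
}

write_mgh <- function(values, path) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  con <- mgh_connection(path, "wb")
  on.exit(close(con))
  header <- c(1L, nrow(m), 1L, 1L, ncol(m), MGH_TYPE_FLOAT, 0L)
  writeBin(header, con, size = 4L, endian = "big")
  ## goodRAS flag (int16 = 0) plus reserved space, zero-filled to offset 284
  writeBin(raw(MGH_HEADER_BYTES - 28L), con)
  v <- as.numeric(m)            # column-major: vertices fastest, then frames
  v[is.na(v)] <- NaN
  writeBin(v, con, size = 4L, endian = "big")
  invisible(path)
}

read_mgh <- function(path) {
  con <- mgh_connection(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "integer", n = 7L, size = 4L, endian = "big")
  if (length(header) < 7L || header[1] != 1L) {
    stop_densim(sprintf("'%s' is not a version-1 MGH overlay", path),
                "densim_format_error")
  }
  if (header[6] != MGH_TYPE_FLOAT) {
    stop_densim(sprintf("'%s': unsupported MGH data type %d (only float32)",
                        path, header[6]),
                "densim_format_error")
  }
  readBin(con, "raw", n = MGH_HEADER_BYTES - 28L)
  n <- prod(header[2:5])
  v <- readBin(con, "numeric", n = n, size = 4L, endian = "big")
  if (length(v) != n) {
    stop_densim(sprintf("'%s' is truncated: expected %d values, found %d",
                        path, n, length(v)),
                "densim_format_error")
  }
  v[is.nan(v)] <- NA_real_
  if (header[5] > 1L) matrix(v, ncol = header[5]) else v
}

write_gifti <- function(values, path) {
  m <- as.matrix(values)
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(ncol(m)))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    v[is.na(v)] <- NaN
    da <- xml2::xml_add_child(doc, "DataArray",
                              Intent = "NIFTI_INTENT_NONE",
                              DataType = "NIFTI_TYPE_FLOAT32",
                              ArrayIndexingOrder = "RowMajorOrder",
                              Dimensionality = "1",
                              Dim0 = as.character(nrow(m)),
                              Encoding = "ASCII",
                              Endian = "LittleEndian")
    data_node <- xml2::xml_add_child(da, "Data")
    xml2::xml_set_text(data_node, paste(format_full(v), collapse = " "))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gifti <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop_densim(sprintf("'%s' is not parseable GIFTI XML: %s", path,
                        conditionMessage(e)),
                "densim_format_error")
  })
  if (xml2::xml_name(doc) != "GIFTI") {
    stop_densim(sprintf("'%s' has no GIFTI root element", path),
                "densim_format_error")
  }
  arrays <- xml2::xml_find_all(doc, "./DataArray")
  if (length(arrays) == 0L) {
    stop_densim(sprintf("'%s' contains no DataArray", path),
                "densim_format_error")
  }
  cols <- lapply(arrays, function(da) {
    enc <- xml2::xml_attr(da, "Encoding")
    if (!identical(enc, "ASCII")) {
      stop_densim(sprintf("'%s': unsupported GIFTI encoding '%s'", path, enc),
                  "densim_format_error")
    }
    dim0 <- as.integer(xml2::xml_attr(da, "Dim0"))
    txt <- xml2::xml_text(xml2::xml_find_first(da, "./Data"))
    v <- as.numeric(strsplit(trimws(txt), "[[:space:]]+")[[1]])
    if (!is.na(dim0) && length(v) != dim0) {
      stop_densim(sprintf("'%s' is truncated: Dim0 = %d but %d values found",
                          path, dim0, length(v)),
                  "densim_format_error")
    }
    v[is.nan(v)] <- NA_real_
    v
  })
  if (length(cols) == 1L) cols[[1]] else do.call(cbind, cols)
}

write_overlay_tsv <- function(values, path) {
  m <- as.matrix(values)
  cn <- colnames(m)
  if (is.null(cn)) cn <- sprintf("v%d", seq_len(ncol(m)))
  lines <- c(paste(cn, collapse = "\t"),
             apply(m, 1L, function(row) {
               paste(format_full(row), collapse = "\t")
             }))
  writeLines(lines, path)
  invisible(path)
}

read_overlay_tsv <- function(path) {
  m <- tryCatch(
    as.matrix(utils::read.delim(path, colClasses = "numeric",
                                check.names = FALSE)),
    error = function(e) {
      stop_densim(sprintf("'%s' is not a numeric dense TSV: %s", path,
                          conditionMessage(e)),
                  "densim_format_error")
    })
  if (ncol(m) == 1L) as.numeric(m[, 1]) else m
}

#' Read a per-vertex surface overlay
#'
#' Reads one scalar value per vertex (or a vertices-by-frames matrix) from
#' an MGH/MGZ, GIFTI, or dense TSV overlay. Missing values (NaN on disk)
#' come back as `NA`.
#'
#' @param path file path; the format is guessed from the extension when
#'   `format = "auto"`.
#' @param format `"auto"`, `"mgh"`, `"gifti"`, or `"tsv"`.
#' @param expected_length required vertex count; a mismatch is an error
#'   naming the file.
#' @return numeric vector (single frame) or matrix (multiple frames).
#' @export
read_overlay <- function(path, format = c("auto", "mgh", "gifti", "tsv"),
                         expected_length = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_densim(sprintf("overlay file '%s' does not exist", path),
                "densim_format_error")
  }
  if (format == "auto") format <- overlay_format_from_path(path)
  out <- switch(format,
                mgh = read_mgh(path),
                gifti = read_gifti(path),
                tsv = read_overlay_tsv(path))
  if (!is.null(expected_length)) {
    n <- if (is.matrix(out)) nrow(out) else length(out)
    if (n != expected_length) {
      stop_densim(sprintf("'%s' has %d vertices, expected %d", path, n,
                          expected_length),
                  "densim_format_error")
    }
  }
  out
}

#' Write a per-vertex surface overlay
#'
#' Inverse of [read_overlay()]. `NA` values are stored as NaN. MGH stores
#' float32 (the format's convention); GIFTI (ASCII encoding) and TSV store
#' full double precision.
#'
#' @param values numeric vector or vertices-by-frames matrix.
#' @param path output file path.
#' @param format `"auto"` (from extension), `"mgh"`, `"gifti"`, or
#'   `"tsv"`.
#' @return the path, invisibly.
#' @export
write_overlay <- function(values, path,
                          format = c("auto", "mgh", "gifti", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- overlay_format_from_path(path)
  switch(format,
         mgh = write_mgh(values, path),
         gifti = write_gifti(values, path),
         tsv = write_overlay_tsv(values, path))
  invisible(path)
}
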