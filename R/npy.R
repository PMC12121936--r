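# Minimal reader/writer for the .npy container format (version 1.0/2.0,
# little-endian, C-order), covering the numeric dtypes Suite2P emits.
# Scope is deliberately narrow: 1- and 2-D arrays of <f4, <f8, <i2, <i4,
# <i8, |b1, |u1. Fortran-order files are transposed on read.

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6)
  if (!identical(as.integer(magic), c(0x93L, 0x4eL, 0x55L, 0x4dL, 0x50L, 0x59L))) {
    abort(sprintf("%s is not an .npy file (bad magic).", path))
  }
  ver <- readBin(con, "integer", n = 2, size = 1, signed = FALSE)
  hlen <- if (ver[1] >= 2) {
    readBin(con, "integer", n = 1, size = 4, endian = "little")
  } else {
    readBin(con, "integer", n = 1, size = 2, signed = FALSE, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", n = hlen))
  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order'\\s*:\\s*True", header)
  shape_str <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("[[:space:]]", "", shape_str), ",")[[1]])
  shape <- shape[!is.na(shape)]
  if (length(shape) == 0) shape <- 1L
  if (length(shape) > 2) {
    abort(sprintf("Only 1-D/2-D .npy arrays are supported (%s has shape (%s)).",
                  path, shape_str))
  }
  n <- prod(shape)
  dat <- switch(descr,
    "<f8" = readBin(con, "double", n = n, size = 8, endian = "little"),
    "<f4" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "<i8" = readBin(con, "double", n = n, size = 8, endian = "little"),
    "<i4" = readBin(con, "integer", n = n, size = 4, endian = "little"),
    "<i2" = readBin(con, "integer", n = n, size = 2, endian = "little"),
    "|b1" = as.logical(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    "|u1" = readBin(con, "integer", n = n, size = 1, signed = FALSE),
    abort(sprintf("Unsupported .npy dtype '%s' in %s.", descr, path))
  )
  if (length(dat) != n) abort(sprintf("Truncated .npy file: %s", path))
  if (length(shape) == 2) {
    dat <- if (fortran) {
      matrix(dat, nrow = shape[1], ncol = shape[2])
    } else {
      # C-order: fastest-varying index is the last one
      matrix(dat, nrow = shape[2], ncol = shape[1]) |> t()
    }
  }
  dat
}

write_npy <- function(x, path, dtype = "<f8") {
  shape <- if (is.matrix(x)) dim(x) else length(x)
  shape_str <- if (length(shape) == 1) {
    sprintf("(%d,)", shape)
  } else {
    sprintf("(%d, %d)", shape[1], shape[2])
  }
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    dtype, shape_str)
  # pad so total of magic(6)+version(2)+hlen(2)+header is a multiple of 64
  total <- 10 + nchar(header) + 1
  pad <- (64 - total %% 64) %% 64
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  vals <- if (is.matrix(x)) as.vector(t(x)) else as.vector(x)  # C-order
  sz <- switch(dtype, "<f8" = 8, "<f4" = 4, "<i4" = 4,
               abort("Unsupported dtype for writing."))
  type <- if (dtype == "<i4") as.integer(vals) else as.double(vals)
  writeBin(type, con, size = sz, endian = "little")
  invisible(path)
}

#' Read traces from a Suite2P output directory
#'
#' Loads the extracted fluorescence array (`F.npy` for the activity channel,
#' `F_chan2.npy` for a second, static channel) from a Suite2P plane directory.
#' All ROIs are returned by default: the pipeline performs its own selection,
#' so Suite2P's `iscell` classification is *not* applied unless
#' `respect_iscell = TRUE`.
#'
#' Suite2P stores its run options in a pickled `ops.npy`, which R cannot
#' parse; if a sibling `ops.json` with an `fs` entry exists it is used for the
#' frame rate, otherwise `frame_rate_hz` is required.
#'
#' @param path Directory containing Suite2P outputs.
#' @param channel `"activity"` (reads `F.npy`) or `"static"` (reads
#'   `F_chan2.npy`).
#' @param frame_rate_hz Frame rate in Hz; optional if `ops.json` provides it.
#' @param respect_iscell If `TRUE` and `iscell.npy` exists, keep only ROIs
#'   Suite2P classified as cells.
#' @return A [trace_matrix()] with ROI ids `"suite2p_<row>"` (0-based Suite2P
#'   row numbers, so ids match Suite2P's own indexing).
#' @export
read_suite2p_dir <- function(path, channel = c("activity", "static"),
                             frame_rate_hz = NULL, respect_iscell = FALSE) {
  channel <- match.arg(channel)
  if (!dir.exists(path)) abort(sprintf("No such directory: %s", path))
  fname <- if (channel == "activity") "F.npy" else "F_chan2.npy"
  fpath <- file.path(path, fname)
  if (!file.exists(fpath)) {
    abort(sprintf("Missing fluorescence file %s in %s.", fname, path))
  }
  values <- read_npy(fpath)
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  if (is.null(frame_rate_hz)) {
    opsj <- file.path(path, "ops.json")
    if (file.exists(opsj)) {
      ops <- jsonlite::read_json(opsj, simplifyVector = TRUE)
      frame_rate_hz <- ops[["fs"]]
    }
    if (is.null(frame_rate_hz)) {
      abort("Frame rate not found (no ops.json with 'fs'); pass `frame_rate_hz`.")
    }
  }
  ids <- paste0("suite2p_", seq_len(nrow(values)) - 1)
  keep <- rep(TRUE, nrow(values))
  if (respect_iscell) {
    icp <- file.path(path, "iscell.npy")
    if (!file.exists(icp)) abort("`respect_iscell = TRUE` but no iscell.npy found.")
    iscell <- read_npy(icp)
    flags <- if (is.matrix(iscell)) iscell[, 1] else iscell
    if (length(flags) != nrow(values)) {
      abort(sprintf(
        "iscell.npy has %d rows but %s has %d ROIs.",
        length(flags), fname, nrow(values)
      ))
    }
    keep <- as.logical(flags > 0)
  }
  trace_matrix(values[keep, , drop = FALSE], frame_rate_hz,
    roi_ids = ids[keep], channel = channel
  )
}
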