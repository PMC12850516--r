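# Minimal NPY (v1.0) codec for numeric arrays, plus dataset serialization as
# NPY + JSON sidecar. Covers double ('<f8') and integer ('<i4'/'<i8') payloads,
# which is all the pipeline's array interchange needs.

#' Write a numeric array to an NPY file
#'
#' Serializes a numeric vector, matrix or array in NumPy's `.npy` v1.0 format
#' (little-endian doubles, Fortran order), so datasets and feature matrices can
#' be exchanged with NumPy-based tooling.
#'
#' @param x Numeric vector, matrix or array.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_npy <- function(x, path) {
  if (!is.numeric(x)) stop_bad_arg("write_npy() handles numeric arrays only")
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  shape_str <- if (length(shape) == 1L) sprintf("(%d,)", shape) else
    sprintf("(%s)", paste(shape, collapse = ", "))
  header <- sprintf("{'descr': '<f8', 'fortran_order': True, 'shape': %s, }",
                    shape_str)
  base_len <- 10L + nchar(header, type = "bytes") + 1L
  pad <- (64L - base_len %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header, type = "bytes")), con, size = 2L,
           endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.double(x), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a numeric array from an NPY file
#'
#' @param path Path to a `.npy` file holding a little-endian float64 or
#'   int32/int64 array.
#' @return A numeric vector/matrix/array with the stored shape.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic[1:6], as.raw(c(0x93, charToRaw("NUMPY")))))
    stop_bad_arg("'%s' is not an NPY file", path)
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- regmatches(header, regexpr("'descr':\\s*'[^']+'", header))
  descr <- sub(".*'descr':\\s*'", "", descr); descr <- sub("'$", "", descr)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- regmatches(header, regexpr("'shape':\\s*\\(([^)]*)\\)", header))
  shape_s <- gsub(".*\\(|\\)", "", shape_s)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  shape <- shape[!is.na(shape)]
  n <- if (length(shape)) prod(shape) else 1L
  x <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4L, endian = "little"),
    "<i8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<i4" = as.double(readBin(con, "integer", n, size = 4L, endian = "little")),
    "|b1" = as.double(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    stop_bad_arg("unsupported NPY dtype '%s'", descr))
  if (length(shape) >= 2L) {
    if (fortran) dim(x) <- shape
    else x <- aperm(array(x, dim = rev(shape)), rev(seq_along(shape)))
  }
  x
}

#' Save a synthetic EEG dataset as NPY arrays plus a JSON sidecar
#'
#' Writes `signal_samples.npy` (n x channels x samples), `is_sz.npy` (labels)
#' and `meta.json` (subject ids, sampling rate, channel count) into `dir`.
#'
#' @param dataset A list of EEG records from [generate_eeg_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
save_eeg_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset)
  ch <- nrow(dataset[[1]]$data); ns <- ncol(dataset[[1]]$data)
  arr <- array(0, dim = c(n, ch, ns))
  for (i in seq_len(n)) arr[i, , ] <- dataset[[i]]$data
  write_npy(arr, file.path(dir, "signal_samples.npy"))
  write_npy(vapply(dataset, function(r) as.double(r$label), 0),
            file.path(dir, "is_sz.npy"))
  meta <- list(fs = dataset[[1]]$fs,
               n_channels = ch,
               subject_id = vapply(dataset, function(r) r$subject_id, ""))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load an EEG dataset stored by [save_eeg_dataset()]
#'
#' @param dir Directory holding `signal_samples.npy`, `is_sz.npy`, `meta.json`.
#' @return A list of EEG records (class `eeg_record`).
#' @export
load_eeg_dataset <- function(dir) {
  arr <- read_npy(file.path(dir, "signal_samples.npy"))
  lab <- read_npy(file.path(dir, "is_sz.npy"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  lapply(seq_len(dim(arr)[1]), function(i)
    eeg_record(arr[i, , ], fs = meta$fs, label = as.integer(lab[i]),
               subject_id = meta$subject_id[i]))
}
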