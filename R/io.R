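#' Read and write square symmetric matrices as TSV
#'
#' Matrices are stored as tab-separated text with region ids as both the
#' header row and the first column. Writing keeps 17 significant digits so
#' a save/load round trip is elementwise exact; loading validates symmetry
#' to 1e-10 (symmetrizing with a warning inside tolerance) and rejects
#' non-square or NaN-bearing files.
#'
#' @param m Square symmetric numeric matrix.
#' @param path File path.
#' @return `load_matrix` returns the matrix with region-id dimnames.
#' @export
save_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(0:(nrow(m) - 1L))
  out <- format(m, digits = 17, scientific = TRUE, trim = TRUE)
  df <- cbind(region_id = ids, as.data.frame(out, stringsAsFactors = FALSE))
  names(df) <- c("region_id", ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname save_matrix
#' @export
load_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (nrow(m) != ncol(m)) {
    stop("format error: matrix in ", path, " is not square (",
         nrow(m), " x ", ncol(m), ")", call. = FALSE)
  }
  if (!identical(colnames(m), ids)) {
    stop("format error: header ids do not match row ids in ", path,
         call. = FALSE)
  }
  if (anyNA(m)) stop("format error: missing values in ", path, call. = FALSE)
  asym <- max(abs(m - t(m)))
  if (asym > 1e-10) {
    stop("format error: matrix in ", path, " is asymmetric (max deviation ",
         format(asym, digits = 3), ")", call. = FALSE)
  }
  if (asym > 0) {
    warning("symmetrizing matrix with asymmetry ", format(asym, digits = 3),
            call. = FALSE)
    m <- (m + t(m)) / 2
  }
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, ids)
  m
}

#' Read and write parcellation tables as TSV
#'
#' Columns: `region_id`, `name`, `hemisphere`, `homolog_id`, `volume`.
#' Loading re-validates the invariants (contiguous ids, symmetric
#' cross-hemisphere homolog mapping, positive volumes).
#'
#' @param parc A parcellation table.
#' @param path File path.
#' @export
save_parcellation <- function(parc, path) {
  validate_parcellation(parc)
  write.table(as.data.frame(parc), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname save_parcellation
#' @export
load_parcellation <- function(path) {
  parc <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  class(parc) <- c("parcellation", "data.frame")
  validate_parcellation(parc)
  parc
}

#' Read and write regional time series as TSV with a metadata sidecar
#'
#' The TSV has region ids as the header row and one row per time point.
#' The sampling interval and subject id travel in a `key=value` sidecar
#' (`<path>.meta`).
#'
#' @param ts A `regional_ts`.
#' @param path File path for the TSV.
#' @export
save_timeseries <- function(ts, path) {
  x <- ts$values
  df <- as.data.frame(format(x, digits = 17, trim = TRUE))
  names(df) <- colnames(x)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("sampling_interval=", format(ts$sampling_interval,
                                                   digits = 17)),
               paste0("subject_id=", ts$subject_id)),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname save_timeseries
#' @export
load_timeseries <- function(path) {
  x <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE))
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("format error: missing values in ", path, call. = FALSE)
  meta_path <- paste0(path, ".meta")
  tr <- 1
  subject <- "unknown"
  if (file.exists(meta_path)) {
    kv <- strsplit(readLines(meta_path), "=", fixed = TRUE)
    meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    if ("sampling_interval" %in% names(meta)) {
      tr <- as.numeric(meta[["sampling_interval"]])
    }
    if ("subject_id" %in% names(meta)) subject <- meta[["subject_id"]]
  }
  structure(list(values = x, sampling_interval = tr, subject_id = subject,
                 states = NULL),
            class = "regional_ts")
}
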