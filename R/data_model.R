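# Core containers, validation and text/binary I/O shared by every stage.
#
# Conventions fixed here once:
#  * matrices on disk are dense TSV (no header, no row names) or raw
#    little-endian float64 row-major with a 2-int32 header (rows, cols);
#  * cluster labels are 0-based in files, 1-based inside R;
#  * zero-one indicator matrices are the canonical in-memory form of a
#    partition (row i one-hot, or all-zero for a missing instance).

SYMMETRY_TOL <- 1e-8

stop_lfimc <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "lfimc_error", "error", "condition")))
}

#' Bundle kernels, visibility mask and optional labels
#'
#' The universe every stage of the pipeline consumes: P symmetric N x N
#' kernel matrices over the same N samples, an N x P zero-one visibility
#' mask S (S\[i, j\] = 1 means the instance of sample i is visible in view
#' j), and optional ground-truth labels for evaluation. Every sample must
#' be visible in at least one view.
#'
#' Kernels with asymmetry at most `1e-8` (max |K - t(K)|) are silently
#' symmetrized as (K + t(K))/2; larger asymmetry is an error. Kernels are
#' not required to be positive semidefinite (the spectral solver only needs
#' symmetry), but a clearly negative smallest eigenvalue triggers a warning
#' when `check_psd = TRUE`.
#'
#' @param kernels list of P symmetric numeric N x N matrices.
#' @param mask N x P zero-one matrix, or NULL for fully visible data.
#' @param sample_ids optional character vector of length N.
#' @param labels optional integer ground-truth labels (length N, 1-based).
#' @param check_psd check and warn about indefinite kernels (default TRUE).
#' @return An object of class `multiview_kernel_data`: a list with elements
#'   `kernels`, `mask`, `sample_ids`, `labels`, `n_samples`, `n_views`.
#' @examples
#' d <- multiview_kernel_data(list(diag(3), diag(3)))
#' d$n_samples; d$n_views
#' @export
multiview_kernel_data <- function(kernels, mask = NULL, sample_ids = NULL,
                                  labels = NULL, check_psd = TRUE) {
  if (!is.list(kernels) || length(kernels) == 0L)
    stop_lfimc("'kernels' must be a non-empty list of matrices", "lfimc_dimension_error")
  kernels <- lapply(kernels, function(k) {
    k <- as.matrix(k)
    storage.mode(k) <- "double"
    dimnames(k) <- NULL
    k
  })
  n <- nrow(kernels[[1L]])
  p <- length(kernels)
  for (j in seq_len(p)) {
    kj <- kernels[[j]]
    if (nrow(kj) != ncol(kj))
      stop_lfimc(sprintf("kernel %d is not square (%d x %d)", j, nrow(kj), ncol(kj)),
                 "lfimc_dimension_error")
    if (nrow(kj) != n)
      stop_lfimc(sprintf("kernel %d has %d samples; kernel 1 has %d", j, nrow(kj), n),
                 "lfimc_dimension_error")
    asym <- max(abs(kj - t(kj)))
    if (asym > SYMMETRY_TOL)
      stop_lfimc(sprintf("kernel %d asymmetry %.3g exceeds tolerance %g", j, asym, SYMMETRY_TOL),
                 "lfimc_symmetry_error")
    kernels[[j]] <- (kj + t(kj)) / 2
  }
  if (is.null(mask)) mask <- matrix(1, n, p)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "double"
  if (!all(dim(mask) == c(n, p)))
    stop_lfimc(sprintf("mask is %d x %d; expected %d x %d", nrow(mask), ncol(mask), n, p),
               "lfimc_dimension_error")
  if (!all(mask %in% c(0, 1)))
    stop_lfimc("mask entries must be 0 or 1", "lfimc_mask_error")
  if (any(rowSums(mask) == 0))
    stop_lfimc("sample has no visible view (all-zero mask row)", "lfimc_mask_error")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(n))
  if (length(sample_ids) != n)
    stop_lfimc("sample_ids length does not match kernel size", "lfimc_dimension_error")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n)
      stop_lfimc("labels length does not match kernel size", "lfimc_dimension_error")
  }
  if (check_psd) {
    for (j in seq_len(p)) {
      ev_min <- min(eigen(kernels[[j]], symmetric = TRUE, only.values = TRUE)$values)
      if (ev_min < -1e-6 * max(1, max(abs(kernels[[j]]))))
        warning(sprintf("kernel %d is not positive semidefinite (min eigenvalue %.3g); the spectral solver only requires symmetry", j, ev_min))
    }
  }
  structure(
    list(kernels = kernels, mask = mask, sample_ids = as.character(sample_ids),
         labels = labels, n_samples = n, n_views = p),
    class = "multiview_kernel_data"
  )
}

#' @export
print.multiview_kernel_data <- function(x, ...) {
  cat(sprintf("multiview_kernel_data: %d samples, %d views\n", x$n_samples, x$n_views))
  vis <- colSums(x$mask)
  cat(sprintf("  visible instances per view: %s\n", paste(vis, collapse = ", ")))
  cat(sprintf("  ground-truth labels: %s\n", if (is.null(x$labels)) "absent" else
    sprintf("present (%d clusters)", length(unique(x$labels)))))
  invisible(x)
}

#' Replace the visibility mask of a multiview kernel set
#'
#' Returns a copy of `data` with `mask` installed (e.g. a simulated
#' incomplete pattern from [generate_mask]). Kernel values are untouched;
#' the mask alone governs which entries downstream stages may read.
#'
#' @param data a `multiview_kernel_data` object.
#' @param mask N x P zero-one matrix with no all-zero row.
#' @return A `multiview_kernel_data` object.
#' @export
set_mask <- function(data, mask) {
  stopifnot(inherits(data, "multiview_kernel_data"))
  multiview_kernel_data(data$kernels, mask, data$sample_ids, data$labels,
                        check_psd = FALSE)
}

#' Per-view partition indicator
#'
#' A zero-one N x K matrix Z encoding the clustering of one view: row i is
#' the one-hot cluster label of sample i, or all-zero when the instance is
#' missing in that view.
#'
#' @param matrix zero-one N x K matrix.
#' @param view_index 1-based index of the view the partition belongs to.
#' @param mask_col optional zero-one vector of length N; when given, rows
#'   are checked to be all-zero exactly where the mask is 0.
#' @return An object of class `view_assignment` with elements `matrix` and
#'   `view_index`.
#' @export
view_assignment <- function(matrix, view_index, mask_col = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (!all(matrix %in% c(0, 1)))
    stop_lfimc("indicator entries must be 0 or 1", "lfimc_validation_error")
  rs <- rowSums(matrix)
  if (!all(rs %in% c(0, 1)))
    stop_lfimc("each indicator row must sum to 0 (missing) or 1", "lfimc_validation_error")
  if (!is.null(mask_col)) {
    if (length(mask_col) != nrow(matrix))
      stop_lfimc("mask column length mismatch", "lfimc_dimension_error")
    if (!all((rs == 0) == (mask_col == 0)))
      stop_lfimc("indicator rows must be all-zero exactly for masked instances",
                 "lfimc_validation_error")
  }
  structure(list(matrix = matrix, view_index = as.integer(view_index)),
            class = "view_assignment")
}

# Accept a list of view_assignment objects or bare indicator matrices.
assignment_matrices <- function(assignments) {
  lapply(assignments, function(a) {
    if (inherits(a, "view_assignment")) a$matrix else as.matrix(a)
  })
}

#' Validate a consensus clustering decision
#'
#' A consensus decision Y is a zero-one N x K matrix with every row summing
#' to exactly 1 (each sample belongs to exactly one cluster).
#'
#' @param y matrix to validate.
#' @return `y` (invisibly standardized to double storage).
#' @export
validate_decision <- function(y) {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  if (nrow(y) == 0L) stop_lfimc("empty decision", "lfimc_validation_error")
  if (!all(y %in% c(0, 1)))
    stop_lfimc("decision entries must be 0 or 1", "lfimc_validation_error")
  if (!all(rowSums(y) == 1))
    stop_lfimc("every decision row must sum to exactly 1", "lfimc_validation_error")
  y
}

#' Convert integer labels to a zero-one indicator matrix
#'
#' @param labels integer vector (1-based labels; NA marks a missing
#'   instance and yields an all-zero row).
#' @param k number of clusters; defaults to `max(labels)`.
#' @return zero-one `length(labels)` x `k` matrix.
#' @export
labels_to_indicator <- function(labels, k = NULL) {
  labels <- as.integer(labels)
  if (is.null(k)) k <- max(labels, na.rm = TRUE)
  n <- length(labels)
  z <- matrix(0, n, k)
  ok <- which(!is.na(labels))
  if (any(labels[ok] < 1L | labels[ok] > k))
    stop_lfimc("labels out of range 1..k", "lfimc_validation_error")
  z[cbind(ok, labels[ok])] <- 1
  z
}

#' Convert an indicator matrix to integer labels
#'
#' @param z zero-one N x K matrix with rows summing to 0 or 1.
#' @return integer vector of 1-based labels; all-zero rows become NA.
#' @export
indicator_to_labels <- function(z) {
  z <- as.matrix(z)
  rs <- rowSums(z)
  lab <- max.col(z, ties.method = "first")
  lab[rs == 0] <- NA_integer_
  as.integer(lab)
}

## ---- file formats -----------------------------------------------------

#' Read / write a dense numeric matrix (TSV or raw float64)
#'
#' Text dialect: tab-separated values, no header, one matrix row per line.
#' Binary dialect: two little-endian int32 (rows, cols) followed by the
#' row-major little-endian float64 payload. `format = "auto"` picks binary
#' for paths ending in `.bin`, text otherwise.
#'
#' @param path file path.
#' @param format one of "auto", "tsv", "bin".
#' @return `read_matrix` returns a numeric matrix.
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "bin")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_lfimc(sprintf("file not found: %s", path), "lfimc_io_error")
  if (format == "auto") format <- if (grepl("\\.bin$", path)) "bin" else "tsv"
  if (format == "bin") {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
    x <- readBin(con, "double", n = hdr[1L] * hdr[2L], size = 8L, endian = "little")
    # payload is row-major; R matrices are column-major
    matrix(x, nrow = hdr[1L], ncol = hdr[2L], byrow = TRUE)
  } else {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "numeric")
    unname(as.matrix(x))
  }
}

#' @rdname read_matrix
#' @param x numeric matrix to write.
#' @export
write_matrix <- function(x, path, format = c("auto", "tsv", "bin")) {
  format <- match.arg(format)
  x <- as.matrix(x)
  if (format == "auto") format <- if (grepl("\\.bin$", path)) "bin" else "tsv"
  if (format == "bin") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.integer(dim(x)), con, size = 4L, endian = "little")
    writeBin(as.double(t(x)), con, size = 8L, endian = "little")
  } else {
    utils::write.table(format(x, digits = 17, scientific = TRUE, trim = TRUE),
                       path, sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(NULL)
}

#' Read a kernel set from files
#'
#' Reads P kernel matrices plus the visibility mask (and optionally
#' ground-truth labels) and returns a validated [multiview_kernel_data]
#' object. Kernels with asymmetry within tolerance are symmetrized.
#'
#' @param paths character vector of kernel matrix files (TSV or .bin).
#' @param mask_path path to the N x P zero-one mask (TSV).
#' @param labels_path optional path to ground-truth labels (one 0-based
#'   integer per line).
#' @param check_psd warn about indefinite kernels (default TRUE).
#' @return a `multiview_kernel_data` object.
#' @export
read_kernel_set <- function(paths, mask_path, labels_path = NULL, check_psd = TRUE) {
  kernels <- lapply(paths, read_matrix)
  mask <- read_matrix(mask_path, format = "tsv")
  labels <- if (!is.null(labels_path)) read_labels(labels_path) else NULL
  multiview_kernel_data(kernels, mask, labels = labels, check_psd = check_psd)
}

#' Read / write cluster labels (0-based on disk, 1-based in R)
#'
#' @param path file path; one integer per line.
#' @return `read_labels` returns an integer vector of 1-based labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path))
    stop_lfimc(sprintf("file not found: %s", path), "lfimc_io_error")
  as.integer(readLines(path)) + 1L
}

#' @rdname read_labels
#' @param labels integer vector of 1-based labels.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(as.integer(labels) - 1L), path)
  invisible(NULL)
}

#' Write a consensus partition with a JSON sidecar
#'
#' Writes one 0-based cluster index per line to `path` and a JSON sidecar
#' `<path>.json` recording N, K and any metadata supplied (e.g. final
#' objective value, iteration count).
#'
#' @param decision zero-one N x K decision matrix (rows sum to 1).
#' @param path output file path for the labels.
#' @param metadata named list merged into the sidecar.
#' @export
write_partition <- function(decision, path, metadata = list()) {
  y <- validate_decision(decision)
  write_labels(indicator_to_labels(y), path)
  side <- c(list(n = nrow(y), k = ncol(y)), metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Read a partition written by [write_partition]
#'
#' @param path path to the labels file; `<path>.json` supplies K when
#'   present, otherwise K defaults to the largest label.
#' @return zero-one indicator matrix.
#' @export
read_partition <- function(path) {
  labels <- read_labels(path)
  side <- paste0(path, ".json")
  k <- if (file.exists(side)) jsonlite::read_json(side)$k else max(labels)
  labels_to_indicator(labels, k)
}
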