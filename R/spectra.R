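#' Construct a single Raman spectrum
#'
#' A spectrum pairs a strictly increasing wavenumber grid (cm^-1) with one
#' intensity trace of the same length. Intensities are in arbitrary counts;
#' the measured range in serum work is typically 500-2000 cm^-1.
#'
#' @param wavenumbers numeric, strictly increasing grid in cm^-1.
#' @param intensities numeric, same length as `wavenumbers`, all finite.
#' @return An object of class `spectrum` (list with `wavenumbers`,
#'   `intensities`).
#' @export
spectrum <- function(wavenumbers, intensities) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop_input("wavenumbers (%d) and intensities (%d) differ in length",
               length(wavenumbers), length(intensities))
  if (!all(is.finite(wavenumbers)) || any(diff(wavenumbers) <= 0))
    stop_input("wavenumbers must be finite and strictly increasing")
  if (!all(is.finite(intensities)))
    stop_input("intensities must all be finite")
  structure(list(wavenumbers = wavenumbers, intensities = intensities),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.1f-%.1f cm^-1, intensity [%.3g, %.3g]\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Construct a spectral dataset
#'
#' Container for a sample-by-wavenumber intensity matrix with optional class
#' labels and a domain tag. This is the unit all preprocessing, training and
#' evaluation functions operate on. Class labels are integer codes starting
#' at 0, with human-readable names carried in `classes`.
#'
#' @param X numeric matrix, samples in rows, one column per grid point.
#' @param y optional integer vector of class codes (0-based), length `nrow(X)`.
#' @param wavenumbers numeric grid shared by all rows (or a plain feature
#'   index after PCA harmonization).
#' @param domain `"source"` or `"target"`.
#' @param classes optional character vector naming class codes `0..k-1`.
#' @param sample_ids optional character ids; generated when missing.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(X, y = NULL, wavenumbers = NULL,
                             domain = c("source", "target"),
                             classes = NULL, sample_ids = NULL) {
  domain <- match.arg(domain)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop_input("X contains non-finite intensities")
  if (is.null(wavenumbers)) wavenumbers <- seq_len(ncol(X))
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != ncol(X))
    stop_input("wavenumbers length (%d) != ncol(X) (%d)",
               length(wavenumbers), ncol(X))
  if (any(diff(wavenumbers) <= 0))
    stop_input("wavenumbers must be strictly increasing")
  if (!is.null(y)) {
    y <- as.integer(y)
    if (length(y) != nrow(X))
      stop_input("length(y) (%d) != nrow(X) (%d)", length(y), nrow(X))
    if (any(y < 0)) stop_input("class codes must be >= 0")
    present <- sort(unique(y))
    if (!identical(present, seq.int(0L, max(y))) && length(present) > 0)
      if (!all(present %in% 0:max(present)))
        stop_input("class codes must be contiguous from 0")
  }
  if (is.null(classes) && !is.null(y)) classes <- paste0("class", 0:max(y))
  if (is.null(sample_ids)) sample_ids <- sprintf("%s_%04d", domain, seq_len(nrow(X)))
  structure(list(X = X, y = y, wavenumbers = wavenumbers, domain = domain,
                 classes = classes, sample_ids = sample_ids),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  lab <- if (is.null(x$y)) "unlabeled" else
    paste(sprintf("%s:%d", x$classes[sort(unique(x$y)) + 1L],
                  tabulate(x$y + 1L, nbins = length(x$classes))[sort(unique(x$y)) + 1L]),
          collapse = ", ")
  cat(sprintf("<spectral_dataset> %s domain, %d x %d (%s)\n",
              x$domain, nrow(x$X), ncol(x$X), lab))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$X)

n_classes <- function(ds) {
  if (!is.null(ds$classes)) return(length(ds$classes))
  if (!is.null(ds$y)) return(max(ds$y) + 1L)
  stop_input("dataset carries neither labels nor a class map")
}

# Row-subset a dataset, keeping metadata in step.
subset_dataset <- function(ds, idx) {
  spectral_dataset(ds$X[idx, , drop = FALSE],
                   y = if (!is.null(ds$y)) ds$y[idx] else NULL,
                   wavenumbers = ds$wavenumbers, domain = ds$domain,
                   classes = ds$classes, sample_ids = ds$sample_ids[idx])
}

# Stack two datasets sharing a grid (labels kept if both carry them).
rbind_datasets <- function(a, b, domain = a$domain) {
  if (!isTRUE(all.equal(a$wavenumbers, b$wavenumbers)))
    stop_input("cannot stack datasets on different grids")
  y <- if (!is.null(a$y) && !is.null(b$y)) c(a$y, b$y) else NULL
  spectral_dataset(rbind(a$X, b$X), y = y, wavenumbers = a$wavenumbers,
                   domain = domain, classes = a$classes %||% b$classes,
                   sample_ids = make.unique(c(a$sample_ids, b$sample_ids)))
}

#' Read spectra from CSV/TSV
#'
#' Expects a header row of wavenumbers and one sample per row. An optional
#' sidecar table supplies `sample_id`, `label` and `domain` columns.
#'
#' @param path main table, comma- or tab-separated (by extension).
#' @param sidecar optional path to a `(sample_id, label, domain)` table.
#' @param domain domain tag used when no sidecar is given.
#' @return A [spectral_dataset()].
#' @export
read_spectra_csv <- function(path, sidecar = NULL, domain = "source") {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           row.names = NULL)
  first_chr <- !is.numeric(tab[[1]])
  ids <- if (first_chr) as.character(tab[[1]]) else NULL
  if (first_chr) tab <- tab[, -1, drop = FALSE]
  wn <- as.numeric(colnames(tab))
  if (any(is.na(wn))) stop_input("header row must contain numeric wavenumbers")
  X <- as.matrix(tab)
  y <- NULL; classes <- NULL
  if (!is.null(sidecar)) {
    side <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
    if (!is.null(ids)) side <- side[match(ids, side$sample_id), ]
    domain <- side$domain[1]
    if (!all(is.na(side$label))) {
      lev <- sort(unique(side$label))
      y <- match(side$label, lev) - 1L
      classes <- as.character(lev)
    }
  }
  spectral_dataset(X, y = y, wavenumbers = wn, domain = domain,
                   classes = classes, sample_ids = ids)
}

#' Write a spectral dataset to CSV (plus optional sidecar)
#'
#' @param ds a [spectral_dataset()].
#' @param path output CSV for the intensity table.
#' @param sidecar optional path for the `(sample_id, label, domain)` table.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(ds, path, sidecar = NULL) {
  tab <- as.data.frame(ds$X)
  colnames(tab) <- sprintf("%.12g", ds$wavenumbers)
  tab <- cbind(sample_id = ds$sample_ids, tab)
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(sidecar)) {
    lab <- if (is.null(ds$y)) NA_character_ else ds$classes[ds$y + 1L]
    utils::write.csv(data.frame(sample_id = ds$sample_ids, label = lab,
                                domain = ds$domain), sidecar, row.names = FALSE)
  }
  invisible(path)
}
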