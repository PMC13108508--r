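#' Structural connectome container
#'
#' Wraps a nonnegative symmetric-in-spirit weight matrix with parcel labels,
#' an optional homotopic pairing (an involution: `pairing[i] = j` implies
#' `pairing[j] = i`) and the normalization record needed to recover raw
#' streamline counts.
#'
#' @param weights N x N nonnegative numeric matrix.
#' @param labels Character vector of unique parcel labels (defaults to
#'   dimnames or `parcel_1..N`).
#' @param pairing Optional integer vector: `pairing[i]` is the index of the
#'   contralateral partner of parcel `i`, `NA` if unpaired.
#' @param normalization Optional list recording how `weights` were derived
#'   from raw counts (see [normalize_connectome()]).
#' @return An object of class `connectome`.
#' @export
connectome <- function(weights, labels = NULL, pairing = NULL,
                       normalization = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be square")
  if (any(!is.finite(weights))) stop("weights must be finite")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels)) labels <- paste0("parcel_", seq_len(n))
  }
  if (length(labels) != n) stop("need one label per parcel")
  if (anyDuplicated(labels)) stop("parcel labels must be unique")
  if (!is.null(pairing)) {
    pairing <- as.integer(pairing)
    if (length(pairing) != n) stop("pairing must have one entry per parcel")
    for (i in seq_len(n)) {
      j <- pairing[i]
      if (!is.na(j) && (j < 1 || j > n || is.na(pairing[j]) ||
                        pairing[j] != i))
        stop("pairing must be an involution over paired parcels")
    }
  }
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels, pairing = pairing,
                 normalization = normalization),
            class = "connectome")
}

#' Normalize a raw streamline-count matrix
#'
#' Divides raw tractography counts by the total number of streamlines and
#' the number of parcels, recording the factors so the operation can be
#' inverted exactly.
#'
#' @param raw_counts N x N nonnegative matrix of streamline counts.
#' @param n_parcels Number of parcels (defaults to `nrow(raw_counts)`).
#' @param total_streamlines Total fiber count (defaults to
#'   `sum(raw_counts)`); must be positive.
#' @param labels,pairing Passed to [connectome()].
#' @return A [connectome()] whose `normalization` record holds
#'   `total_streamlines` and `n_parcels`.
#' @export
normalize_connectome <- function(raw_counts, n_parcels = nrow(raw_counts),
                                 total_streamlines = sum(raw_counts),
                                 labels = NULL, pairing = NULL) {
  raw_counts <- as.matrix(raw_counts)
  if (any(raw_counts < 0)) stop("raw counts must be nonnegative")
  if (!is.finite(total_streamlines) || total_streamlines <= 0)
    stop("total streamline count must be positive")
  w <- raw_counts / (total_streamlines * n_parcels)
  connectome(w, labels = labels, pairing = pairing,
             normalization = list(total_streamlines = total_streamlines,
                                  n_parcels = n_parcels))
}

#' Recover raw counts from a normalized connectome
#'
#' Algebraic inverse of [normalize_connectome()] using the stored record.
#'
#' @param con A [connectome()] with a normalization record.
#' @return The raw count matrix.
#' @export
denormalize_connectome <- function(con) {
  if (is.null(con$normalization))
    stop("connectome has no normalization record")
  con$weights * con$normalization$total_streamlines *
    con$normalization$n_parcels
}

#' Normalized receptor-density map
#'
#' Per-parcel serotonin-2A receptor densities normalized to `[0, 1]`.
#'
#' @param values Numeric vector of densities in `[0, 1]`.
#' @param labels Parcel labels (defaults to names or `parcel_1..N`).
#' @return An object of class `receptor_map`.
#' @export
receptor_map <- function(values, labels = NULL) {
  if (any(!is.finite(values))) stop("receptor densities must be finite")
  if (any(values < 0) || any(values > 1))
    stop("receptor densities must lie in [0, 1]")
  if (is.null(labels)) {
    labels <- names(values)
    if (is.null(labels)) labels <- paste0("parcel_", seq_along(values))
  }
  if (anyDuplicated(labels)) stop("parcel labels must be unique")
  structure(list(values = stats::setNames(as.numeric(values), labels),
                 labels = labels),
            class = "receptor_map")
}

#' Min-max normalize raw receptor densities
#'
#' Maps raw (e.g. Bmax) densities linearly onto `[0, 1]` so that the
#' minimum is exactly 0 and the maximum exactly 1.
#'
#' @param values Raw nonnegative densities (not constant).
#' @param labels Optional parcel labels.
#' @return A [receptor_map()].
#' @export
normalize_receptor_map <- function(values, labels = NULL) {
  rng <- range(values)
  if (diff(rng) <= 0) stop("densities are constant; cannot normalize")
  receptor_map((values - rng[1]) / diff(rng), labels)
}

#' Write a labelled matrix as delimited text
#'
#' Tab-separated matrix with a header row and a leading label column, as
#' used for connectome weights, FC matrices and leadfields.
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled matrix from delimited text
#'
#' @param path File written by [write_matrix_tsv()].
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a receptor map from two-column text
#'
#' @param path Tab-separated file with columns `label` and `value`.
#' @return A [receptor_map()].
#' @export
read_receptor_map <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  receptor_map(df[[2]], labels = df[[1]])
}

#' Write a receptor map as two-column text
#'
#' @param map A [receptor_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_receptor_map <- function(map, path) {
  write.table(data.frame(label = map$labels, value = unname(map$values)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
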