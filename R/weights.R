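#' Smallest distance band leaving no unit isolated
#'
#' The maximum over units of the distance to their nearest neighbour: the
#' smallest distance band under which every unit has at least one
#' neighbour (the minimum-spanning-distance rule).
#'
#' @param coords two-column matrix or data.frame of planar coordinates.
#' @return positive scalar distance.
#' @export
critical_band <- function(coords) {
  coords <- check_numeric_matrix_coords(coords)
  if (nrow(coords) < 2L)
    stop_gtwr("invalid_config", "need at least 2 units")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  max(apply(d, 1L, min))
}

#' Build a spatial weights matrix
#'
#' Constructs neighbour weights over one cross-section of units from their
#' planar coordinates. Three schemes:
#' \describe{
#'   \item{`knn`}{each unit gets exactly `k` nearest neighbours with unit
#'     weight; distance ties are broken by unit (id) order.}
#'   \item{`distance_band`}{unit weight for every pair within `band`.}
#'   \item{`inverse_distance`}{weight `d^(-decay_power)` for pairs within
#'     `band`.}
#' }
#' `band = NULL` defaults to [critical_band()], so every unit has a
#' neighbour. Self-weights are zero unless `include_self = TRUE` (the Gi*
#' variant), which sets `w_ii = 1` before any row standardisation. Units
#' left with no neighbour raise a named warning (`isolated_units`) and keep
#' an all-zero row; downstream statistics drop them explicitly.
#'
#' @param coords two-column matrix or data.frame of planar coordinates.
#' @param scheme `"inverse_distance"`, `"knn"` or `"distance_band"`.
#' @param k neighbour count for `knn`.
#' @param band distance band; `NULL` for the critical band.
#' @param decay_power positive exponent for `inverse_distance`.
#' @param row_standardize scale each non-empty row to sum to 1?
#' @param include_self include `w_ii = 1` (required by Gi*)?
#' @param ids optional unit identifiers (default `1..n`).
#' @return object of class `spatial_weights`: a list with the sparse
#'   matrix `W` (`Matrix::dgCMatrix`), `scheme`, `row_standardized`,
#'   `includes_self`, `ids`, `n`.
#' @export
#' @examples
#' xy <- cbind(runif(20, 0, 100), runif(20, 0, 100))
#' w <- build_weights(xy, scheme = "knn", k = 4)
#' Matrix::rowSums(w$W)  # all 1 after row standardisation
build_weights <- function(coords,
                          scheme = c("inverse_distance", "knn",
                                     "distance_band"),
                          k = 5L, band = NULL, decay_power = 1,
                          row_standardize = TRUE, include_self = FALSE,
                          ids = NULL) {
  scheme <- match.arg(scheme)
  coords <- check_numeric_matrix_coords(coords)
  n <- nrow(coords)
  if (n < 2L) stop_gtwr("invalid_config", "need at least 2 units")
  if (is.null(ids)) ids <- seq_len(n)
  if (anyDuplicated(ids)) stop_gtwr("invalid_config", "ids must be distinct")

  d <- as.matrix(stats::dist(coords))
  W <- matrix(0, n, n)
  if (scheme == "knn") {
    k <- as.integer(k)
    if (k >= n)
      stop_gtwr("invalid_config", "k (%d) must be < number of units (%d)",
                k, n)
    if (k < 1L) stop_gtwr("invalid_config", "k must be >= 1")
    for (i in seq_len(n)) {
      cand <- setdiff(seq_len(n), i)
      ord <- cand[order(d[i, cand], cand)]   # ties broken by id order
      W[i, ord[seq_len(k)]] <- 1
    }
  } else {
    if (is.null(band)) band <- critical_band(coords)
    if (!is.numeric(band) || band <= 0)
      stop_gtwr("invalid_config", "band must be positive")
    inb <- d <= band
    diag(inb) <- FALSE
    if (scheme == "distance_band") {
      W[inb] <- 1
    } else {
      if (decay_power <= 0)
        stop_gtwr("invalid_config", "decay_power must be positive")
      W[inb] <- d[inb]^(-decay_power)
    }
  }

  if (include_self) diag(W) <- 1
  rs <- rowSums(W)
  isolated <- which(rs == 0)
  if (length(isolated))
    warn_gtwr("isolated_units",
              "%d unit(s) have no neighbours: %s", length(isolated),
              paste(utils::head(ids[isolated], 5L), collapse = ", "))
  if (row_standardize) {
    nz <- rs > 0
    W[nz, ] <- W[nz, , drop = FALSE] / rs[nz]
  }
  structure(list(W = methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                                             "generalMatrix"), "CsparseMatrix"),
                 scheme = scheme, row_standardized = isTRUE(row_standardize),
                 includes_self = isTRUE(include_self), ids = ids, n = n,
                 isolated = isolated),
            class = "spatial_weights")
}

#' @export
#' @method print spatial_weights
print.spatial_weights <- function(x, ...) {
  nnz <- Matrix::nnzero(x$W)
  cat(sprintf("Spatial weights: %d units, scheme %s, %d links (%.1f per unit)\n",
              x$n, x$scheme, nnz, nnz / x$n))
  cat(sprintf("  row standardised: %s; self-included: %s; isolates: %d\n",
              x$row_standardized, x$includes_self, length(x$isolated)))
  invisible(x)
}

#' Export / import spatial weights as a sparse triplet table
#'
#' @param w a `spatial_weights` object.
#' @param path CSV path.
#' @return `write_weights` returns `path` invisibly; `read_weights_triplets`
#'   returns a data.frame with columns `i`, `j`, `w` (unit ids).
#' @export
write_weights <- function(w, path) {
  stopifnot(inherits(w, "spatial_weights"))
  tr <- Matrix::summary(w$W)
  out <- data.frame(i = w$ids[tr$i], j = w$ids[tr$j], w = tr$x)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights_triplets <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
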