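#' Construct a weighted directed connectome graph
#'
#' The central container of the package: an n x n nonnegative weight matrix
#' (rows = source areas, columns = target areas), unique node labels, optional
#' 3D coordinates (e.g. injection centroids, in mm), and free-form provenance
#' metadata. Weights are typically FLNe fractions in (0, 1]; the diagonal is
#' exactly zero (no self-projections).
#'
#' @param weights numeric n x n matrix, nonnegative, zero diagonal.
#' @param labels character vector of n unique node names. Defaults to the
#'   rownames of `weights`, or `"n1"..."nN"` if absent.
#' @param coords optional numeric n x 3 matrix of node coordinates (mm).
#' @param meta named list of provenance information.
#' @param fractional if `TRUE`, weights are checked to be at most 1
#'   (FLNe-style fractions).
#' @return An object of class `connectome_graph` with elements `weights`,
#'   `labels`, `coords`, `meta`.
#' @export
connectome_graph <- function(weights, labels = NULL, coords = NULL,
                             meta = list(), fractional = FALSE) {
  weights <- as.matrix(weights)
  if (!is.numeric(weights)) stop("weights must be numeric")
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weight matrix must be square")
  if (anyNA(weights)) stop("weights contain missing values; use load_connectome(pairwise_complete = TRUE)")
  if (any(weights < 0)) stop("negative weight encountered")
  if (any(diag(weights) != 0)) stop("diagonal must be exactly zero (no self-loops)")
  if (fractional && any(weights > 1)) stop("fractional weights must be <= 1")
  if (is.null(labels)) labels <- rownames(weights)
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must have length n")
  if (anyDuplicated(labels)) stop("labels must be unique")
  dimnames(weights) <- list(labels, labels)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3) stop("coords must be n x 3")
    if (!is.numeric(coords) || anyNA(coords)) stop("coords must be finite numeric")
    rownames(coords) <- labels
  }
  structure(list(weights = weights, labels = labels, coords = coords,
                 meta = meta),
            class = "connectome_graph")
}

#' @export
print.connectome_graph <- function(x, ...) {
  m <- sum(x$weights > 0)
  cat(sprintf("<connectome_graph> %d nodes, %d directed edges (density %.3f)\n",
              n_nodes(x), m, m / (n_nodes(x) * (n_nodes(x) - 1))))
  if (!is.null(x$coords)) cat("  with 3D coordinates\n")
  invisible(x)
}

#' Number of nodes of a connectome graph
#' @param g a `connectome_graph`.
#' @return integer node count.
#' @export
n_nodes <- function(g) length(g$labels)

#' Number of directed edges (positive weights)
#' @param g a `connectome_graph`.
#' @return integer edge count.
#' @export
n_edges <- function(g) sum(g$weights > 0)

#' Load a connectome matrix (and optional coordinates) from delimited text
#'
#' Reads a labeled square matrix: first row and first column carry node
#' labels. Empty cells and `NA` are treated as "connection not tested"
#' (missing), which is distinct from a literal `0` ("tested, absent").
#' With `pairwise_complete = TRUE`, nodes are greedily dropped (most untested
#' entries first) until the remaining submatrix has pairwise-complete
#' connection values.
#'
#' @param weights_path path to a CSV/TSV labeled matrix (delimiter sniffed
#'   from the extension/content: `,` or tab).
#' @param coords_path optional path to a CSV with columns label,x,y,z.
#' @param pairwise_complete drop nodes with any untested (missing) entry.
#' @param fractional check weights are <= 1 (FLNe fractions).
#' @return a [connectome_graph()].
#' @export
load_connectome <- function(weights_path, coords_path = NULL,
                            pairwise_complete = TRUE, fractional = FALSE) {
  sep <- if (grepl("\\.tsv$", weights_path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(weights_path, sep = sep, header = TRUE,
                          row.names = 1, check.names = FALSE,
                          na.strings = c("NA", ""), comment.char = "")
  w <- as.matrix(df)
  if (nrow(w) != ncol(w)) stop("non-square matrix: ", nrow(w), " x ", ncol(w))
  if (!identical(rownames(w), colnames(w)))
    stop("row labels and column labels disagree")
  if (pairwise_complete && anyNA(w)) {
    diag(w) <- ifelse(is.na(diag(w)), 0, diag(w))  # untested self-entries are structural zeros
    # greedily drop the node with the most untested entries until the
    # remaining submatrix is pairwise complete
    dropped <- 0L
    while (anyNA(w)) {
      miss <- rowSums(is.na(w)) + colSums(is.na(w))
      w <- w[-which.max(miss), -which.max(miss), drop = FALSE]
      dropped <- dropped + 1L
    }
  } else dropped <- 0L
  coords <- NULL
  if (!is.null(coords_path)) {
    cd <- utils::read.csv(coords_path, header = TRUE)
    if (ncol(cd) < 4) stop("coordinate file must have columns label,x,y,z")
    rownames(cd) <- as.character(cd[[1]])
    missing_lab <- setdiff(rownames(w), rownames(cd))
    if (length(missing_lab))
      stop("coordinates missing for nodes: ", paste(missing_lab, collapse = ", "))
    coords <- as.matrix(cd[rownames(w), 2:4])
  }
  connectome_graph(w, labels = rownames(w), coords = coords,
                   meta = list(source = weights_path,
                               nodes_dropped_incomplete = dropped),
                   fractional = fractional)
}

#' Write a connectome to delimited text
#'
#' Inverse of [load_connectome()]: writes the labeled weight matrix (full
#' stored precision), optional coordinates, and a JSON metadata sidecar.
#'
#' @param g a `connectome_graph`.
#' @param weights_path output CSV path.
#' @param coords_path optional output CSV for coordinates.
#' @param meta_path optional output path for a JSON metadata sidecar.
#' @return `weights_path`, invisibly.
#' @export
write_connectome <- function(g, weights_path, coords_path = NULL,
                             meta_path = NULL) {
  w <- format(g$weights, digits = 17, trim = TRUE, scientific = TRUE)
  tab <- cbind(label = g$labels, w)
  utils::write.table(tab, weights_path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = c("", g$labels))
  if (!is.null(coords_path)) {
    if (is.null(g$coords)) stop("graph has no coordinates")
    utils::write.csv(data.frame(label = g$labels, x = g$coords[, 1],
                                y = g$coords[, 2], z = g$coords[, 3]),
                     coords_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(meta_path))
    jsonlite::write_json(g$meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(weights_path)
}

#' Logarithmic weight-to-length mapping
#'
#' Maps connection weights to lengths so that strong connections are short:
#' `length_ij = -ln(w_ij / w_max)` for positive weights and `Inf` for absent
#' edges. The mapping is order-reversing (strictly antitone) on the positive
#' support, with length 0 exactly at the maximum weight.
#'
#' @param g a `connectome_graph`.
#' @return n x n numeric length matrix (`Inf` marks absent edges; the
#'   diagonal is 0 by convention).
#' @export
weight_to_length <- function(g) {
  w <- g$weights
  wmax <- max(w)
  if (wmax <= 0) stop("all-zero weight matrix has no length transform")
  L <- matrix(Inf, nrow(w), ncol(w), dimnames = dimnames(w))
  pos <- w > 0
  L[pos] <- -log(w[pos] / wmax)
  diag(L) <- 0
  L
}

#' Symmetrize a directed connectome
#'
#' @param g a `connectome_graph`.
#' @param rule `"max"` (elementwise max of the two directions), `"mean"`
#'   (their average), or `"or-binary"` (1 iff either direction is nonzero).
#' @return a `connectome_graph` with a symmetric weight matrix.
#' @export
symmetrize <- function(g, rule = c("max", "mean", "or-binary")) {
  rule <- match.arg(rule)
  w <- g$weights
  s <- switch(rule,
    "max" = pmax(w, t(w)),
    "mean" = (w + t(w)) / 2,
    "or-binary" = (w > 0 | t(w) > 0) + 0)
  meta <- g$meta
  meta$symmetrized <- rule
  connectome_graph(s, labels = g$labels, coords = g$coords, meta = meta)
}

#' Euclidean inter-areal distance matrix
#'
#' @param coords numeric n x 3 matrix of node coordinates (mm), or a
#'   `connectome_graph` carrying coordinates.
#' @return symmetric n x n distance matrix (mm) with zero diagonal.
#' @export
interareal_distances <- function(coords) {
  if (inherits(coords, "connectome_graph")) {
    if (is.null(coords$coords)) stop("graph has no coordinates")
    coords <- coords$coords
  }
  coords <- as.matrix(coords)
  if (anyNA(coords) || any(!is.finite(coords))) stop("coordinates must be finite")
  as.matrix(stats::dist(coords))
}

#' Directed and undirected connection density
#'
#' @param g a `connectome_graph`.
#' @return list with `directed` (edges / n(n-1)) and `undirected`
#'   (node pairs connected in at least one direction / n(n-1)/2).
#' @export
density_connectome <- function(g) {
  n <- n_nodes(g)
  a <- g$weights > 0
  und <- a | t(a)
  list(directed = sum(a) / (n * (n - 1)),
       undirected = sum(und[upper.tri(und)]) / (n * (n - 1) / 2))
}
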