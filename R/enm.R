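#' @title Gaussian network model construction and slow modes
#' @description
#' The coarse-grained elastic network places one node per residue at its
#' C-alpha and connects node pairs within a distance cutoff by identical
#' springs (spring constant 1). Its Kirchhoff (graph Laplacian) matrix has
#' off-diagonal entries -1 for contacts and node degrees on the diagonal; the
#' nonzero eigenvalues of this matrix are the squared mode frequencies of the
#' Gaussian network model, the slowest of which describe global motions.
#' @name enm
NULL

#' Build network nodes from a curated model
#'
#' One node per residue, placed at the C-alpha. Retained hetero residues
#' without a C-alpha (e.g. a nucleotide kept as an extra node) are placed at
#' their heavy-atom centroid.
#'
#' @param model a curated [allo_structure].
#' @return an `allo_nodes` list: `coords` (n x 3 matrix), `labels` (residue
#'   keys), `n_core` (number of reference nodes; equals residue count here).
#' @export
build_nodes <- function(model) {
  rt <- residue_table(model)
  coords <- matrix(NA_real_, nrow(rt), 3L)
  a <- model$atoms
  for (i in seq_len(nrow(rt))) {
    k <- rt$key[i]
    ca <- a$elety == "CA" & !a$is_hydrogen & a$key == k
    if (any(ca)) {
      coords[i, ] <- as.numeric(a[which(ca)[1L], c("x", "y", "z")])
    } else {
      coords[i, ] <- colMeans(residue_heavy_coords(model, k))
    }
  }
  structure(list(coords = coords, labels = rt$key, n_core = nrow(rt)),
            class = "allo_nodes")
}

#' Build the Kirchhoff (connectivity) matrix
#'
#' Entry (i, j) is -1 when nodes i and j are within `cutoff` of each other
#' (closed boundary), the diagonal holds node degrees, and every row sums to
#' exactly zero. Entries are exact integers; the uniform spring constant is 1
#' (eigenvalue ratios are invariant to it).
#'
#' @param nodes an `allo_nodes` object (or a plain n x 3 coordinate matrix).
#' @param cutoff spring cutoff in Angstrom (default 10).
#' @return an `allo_kirchhoff` list: `matrix` (dense symmetric), `cutoff`.
#' @export
build_kirchhoff <- function(nodes, cutoff = 10) {
  coords <- if (inherits(nodes, "allo_nodes")) nodes$coords else as.matrix(nodes)
  stopifnot(nrow(coords) >= 2L, cutoff > 0)
  d <- as.matrix(stats::dist(coords))
  K <- -(d <= cutoff) * 1
  diag(K) <- 0
  diag(K) <- -rowSums(K)
  structure(list(matrix = K, cutoff = cutoff,
                 labels = if (inherits(nodes, "allo_nodes")) nodes$labels else NULL),
            class = "allo_kirchhoff")
}

# Connected components of the contact graph by breadth-first flood fill.
kirchhoff_components <- function(K) {
  A <- K$matrix < 0
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(A[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Eigen-decompose a Kirchhoff matrix into slow modes
#'
#' Returns ascending eigenvalues and orthonormal eigenvectors, counts the
#' zero modes (one per connected network component), and records the indices
#' of the `n_modes` slowest nonzero modes. A disconnected network is an
#' error (condition class `allo_disconnected_error`, carrying component
#' sizes): z-scores of the essential-site scan are undefined across
#' components.
#'
#' @param K an `allo_kirchhoff`.
#' @param n_modes number of slow nonzero modes required (default 10).
#' @param zero_tol zero-mode tolerance, relative to the largest eigenvalue
#'   (default 1e-8).
#' @param method `"dense"` (LAPACK full decomposition, the default) or
#'   `"sparse"` (ARPACK shift-invert via a sparse Cholesky factor; computes
#'   only the slow end of the spectrum).
#' @return an `allo_modes` list: `values` (ascending), `vectors` (columns,
#'   dense method only), `n_zero`, `k_slowest` (indices into `values`).
#' @export
compute_modes <- function(K, n_modes = 10L, zero_tol = 1e-8,
                          method = c("dense", "sparse")) {
  method <- match.arg(method)
  stopifnot(inherits(K, "allo_kirchhoff"), n_modes >= 1L)
  n <- nrow(K$matrix)
  comp <- kirchhoff_components(K)
  if (max(comp) > 1L) {
    sizes <- as.integer(table(comp))
    stop(errorCondition(
      paste0("elastic network is disconnected: ", max(comp),
             " components of sizes ", paste(sizes, collapse = ", ")),
      class = c("allo_disconnected_error", "error", "condition"),
      component_sizes = sizes))
  }
  n_zero_expect <- 1L
  need <- n_zero_expect + n_modes
  if (n < need) {
    stop("network too small: ", n, " nodes cannot yield ", n_modes,
         " nonzero modes", call. = FALSE)
  }
  if (method == "dense") {
    eig <- eigen(K$matrix, symmetric = TRUE)
    values <- rev(eig$values)
    vectors <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
  } else {
    vals <- arpack_smallest(K$matrix, k = need)
    values <- vals
    vectors <- NULL
  }
  tol <- zero_tol * max(abs(values))
  n_zero <- sum(values < tol)
  if (n_zero != n_zero_expect) {
    stop("zero-mode count (", n_zero, ") does not match component count (",
         n_zero_expect, "); adjust zero_tol", call. = FALSE)
  }
  k_slowest <- seq.int(n_zero + 1L, n_zero + n_modes)
  structure(list(values = values, vectors = vectors, n_zero = n_zero,
                 k_slowest = k_slowest, method = method),
            class = "allo_modes")
}

# Smallest k eigenvalues of a symmetric PSD matrix by ARPACK shift-invert:
# the largest eigenvalues of (K + sigma I)^-1 map to the smallest of K.
arpack_smallest <- function(K, k, sigma = NULL) {
  n <- nrow(K)
  if (is.null(sigma)) sigma <- 1e-3 * max(1, mean(diag(K)))
  Ks <- methods::as(Matrix::forceSymmetric(Matrix::Matrix(K, sparse = TRUE)),
                    "CsparseMatrix")
  ch <- Matrix::Cholesky(Ks + Matrix::Diagonal(n) * sigma, LDL = FALSE)
  fn <- function(x, extra) as.numeric(Matrix::solve(ch, x))
  res <- igraph::arpack(fn, sym = TRUE,
                        options = list(n = n, nev = k,
                                       ncv = min(n, max(2L * k + 10L, 20L)),
                                       which = "LA", maxiter = 10000L))
  sort(1 / res$values - sigma)
}

#' Nonzero slow eigenvalues of a mode set
#'
#' @param modes an `allo_modes` object.
#' @return numeric vector of the slowest nonzero eigenvalues (ascending).
#' @export
slow_eigenvalues <- function(modes) {
  stopifnot(inherits(modes, "allo_modes"))
  modes$values[modes$k_slowest]
}

#' Export a Kirchhoff matrix in MatrixMarket format
#'
#' @param K an `allo_kirchhoff`.
#' @param path output `.mtx` path.
#' @return invisibly, the path.
#' @export
write_kirchhoff_mtx <- function(K, path) {
  Matrix::writeMM(Matrix::Matrix(K$matrix, sparse = TRUE), path)
  invisible(path)
}
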