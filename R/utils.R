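#' Vectorize the upper triangle of a symmetric matrix
#'
#' Edge features are stored column-major over the strict upper triangle
#' (the `upper.tri` order), the package-wide convention for window
#' vectors and state centroids.
#'
#' @param m symmetric matrix.
#' @return numeric vector of length `n*(n-1)/2`.
#' @seealso [upperTriMat()] for the inverse.
#' @export
upperTriVec <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[upper.tri(m)]
}

#' Rebuild a symmetric zero-diagonal matrix from an upper-triangle vector
#'
#' @param v edge vector as produced by [upperTriVec()].
#' @param nNodes node count; `length(v)` must equal `nNodes*(nNodes-1)/2`.
#' @return symmetric `nNodes x nNodes` matrix with zero diagonal.
#' @export
upperTriMat <- function(v, nNodes) {
  if (length(v) != nNodes * (nNodes - 1) / 2)
    stop("edge vector length does not match nNodes*(nNodes-1)/2")
  m <- matrix(0, nNodes, nNodes)
  m[upper.tri(m)] <- v
  m + t(m)
}

## Dirichlet sampler (via gamma representation); used for subject-level
## perturbation of group transition rows.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) { # degenerate alphas: fall back to point mass
    g[which.max(alpha)] <- 1
  }
  g / sum(g)
}

## Deterministic child-seed expansion from one master seed. Keeps every
## derived seed a valid 32-bit integer.
deriveSeeds <- function(seed, n) {
  withr::with_seed(as.integer(seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

## Default node metadata: nodes assigned round-robin to subnetwork blocks,
## centroids drawn on a deterministic grid (mm scale) so distance-weighted
## cost is well defined for synthetic cohorts.
defaultNodeMeta <- function(nNodes, networkLabels = NULL) {
  if (is.null(networkLabels)) {
    blocks <- c("Aud", "ECN", "DMN", "SM", "SN", "Visual", "Cerebellar",
                "Other")
    nb <- max(2L, min(length(blocks), nNodes %/% 2L))
    networkLabels <- rep(blocks[seq_len(nb)], length.out = nNodes)
  }
  idx <- seq_len(nNodes) - 1L
  data.frame(
    node = sprintf("N%02d", seq_len(nNodes)),
    network = networkLabels,
    x = 20 * (idx %% 5L) - 40,
    y = 20 * ((idx %/% 5L) %% 5L) - 40,
    z = 15 * (idx %/% 25L),
    stringsAsFactors = FALSE)
}

## md5 of an R object via its serialized text representation; used for
## provenance headers. tools::md5sum works on files, so round-trip one.
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(dput(x)), f)
  unname(tools::md5sum(f))
}
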