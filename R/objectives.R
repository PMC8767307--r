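#' @include AllClasses.R
NULL

#' Cosine similarity
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return the cosine of the angle between `u` and `v`, in \[-1, 1\].
#' @export
cosineSimilarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity is undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

# Row-normalize a matrix of projection vectors.
.unitRows <- function(z) {
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0)) stop("projection vectors must be non-zero")
  z / nrm
}

# Per-anchor contrastive loss with arbitrary positive set.
# z: n x d matrix of projections (rows are views); i anchor; P positive
# indices; A candidate indices (defaults to all but i).
.anchorLoss <- function(z, i, P, temperature, A = NULL) {
  n <- nrow(z)
  if (is.null(A)) A <- setdiff(seq_len(n), i)
  if (length(P) == 0L) stop("positive set P(i) must be non-empty")
  if (!all(P %in% A)) stop("P(i) must be a subset of the candidate set A(i)")
  if (i %in% A) stop("the anchor cannot be its own candidate")
  u <- .unitRows(z)
  s <- drop(u[A, , drop = FALSE] %*% u[i, ]) / temperature
  m <- max(s)
  e <- exp(s - m)
  -log(mean(e[match(P, A)]) / sum(e))
}

#' Normalised temperature-scaled cross entropy (NT-Xent) for one anchor
#'
#' The loss of anchor `i` with its single positive `j`:
#' `-log( exp(sim(z_i, z_j)/T) / sum_{a in A(i)} exp(sim(z_i, z_a)/T) )`,
#' where `sim` is cosine similarity and `A(i)` contains every view in the
#' batch except the anchor itself.
#'
#' @param z numeric matrix of projection vectors, one view per row.
#' @param i anchor row index.
#' @param j positive row index (must belong to `A`).
#' @param temperature softmax temperature `T > 0`.
#' @param A candidate index set `A(i)`; defaults to all rows except `i`.
#' @return non-negative scalar loss.
#' @seealso [supCon()], [contrastiveLoss()]
#' @export
ntXent <- function(z, i, j, temperature = 0.5, A = NULL) {
  stopifnot(length(j) == 1L, temperature > 0)
  .anchorLoss(z, i, j, temperature, A)
}

#' Supervised-contrastive loss for one anchor
#'
#' Generalises [ntXent()] to several positives: the similarity ratios of
#' all positives `p` in `P(i)` are averaged \emph{inside} the logarithm,
#' `-log( (1/|P(i)|) sum_p exp(sim(z_i,z_p)/T) / sum_a exp(sim(z_i,z_a)/T) )`.
#' With a single positive it reduces exactly to NT-Xent.
#'
#' @inheritParams ntXent
#' @param P integer vector of positive row indices (subset of `A`).
#' @return scalar loss.
#' @export
supCon <- function(z, i, P, temperature = 0.5, A = NULL) {
  stopifnot(temperature > 0)
  .anchorLoss(z, i, P, temperature, A)
}

#' Batch contrastive loss and its gradient
#'
#' Mean anchor loss over all views of a batch (both views of a pair serve
#' as anchors), with the exact analytic gradient with respect to the raw
#' (un-normalised) projection matrix — including the Jacobian of the row
#' normalisation.  Used by the pre-training loop; the per-anchor functions
#' [ntXent()] and [supCon()] are the reference surface it is tested
#' against.
#'
#' @param z numeric matrix, one projection vector per view.
#' @param positiveSets list of integer vectors, `P(i)` per row of `z`.
#' @param temperature softmax temperature.
#' @return list with `loss` (scalar) and `grad` (matrix like `z`).
#' @export
contrastiveLoss <- function(z, positiveSets, temperature = 0.5) {
  n <- nrow(z)
  stopifnot(length(positiveSets) == n, temperature > 0)
  u <- .unitRows(z)
  s <- (u %*% t(u)) / temperature
  diag(s) <- -Inf                       # exclude the anchor itself
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  diag(e) <- 0
  denom <- rowSums(e)
  loss <- 0
  g <- matrix(0, n, n)                  # dL/dS
  for (i in seq_len(n)) {
    P <- positiveSets[[i]]
    if (length(P) == 0L) stop(sprintf("P(%d) is empty", i))
    if (i %in% P) stop(sprintf("P(%d) contains the anchor", i))
    num <- mean(e[i, P])
    loss <- loss - log(num / denom[i])
    w <- numeric(n)
    w[P] <- e[i, P] / sum(e[i, P])
    g[i, ] <- (e[i, ] / denom[i] - w) / n
  }
  loss <- loss / n
  # S = U U^T / T and S enters through both its rows and columns.
  gu <- (g + t(g)) %*% u / temperature
  # back through row normalisation: u = z / |z|
  nrm <- sqrt(rowSums(z^2))
  dot <- rowSums(gu * u)
  grad <- (gu - u * dot) / nrm
  list(loss = loss, grad = grad)
}
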