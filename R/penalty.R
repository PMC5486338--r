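#' Penalty (prior precision) blocks
#'
#' A `penalty_block` packages the structure matrix K of a Gaussian Markov
#' random field prior \eqn{f | \tau^2 \sim N(0, (K/\tau^2)^-)} together with
#' its rank and null-space constraints.  Three kinds are used:
#' second-order random walk (`rw2`) for smooth functions of a continuous
#' covariate, intrinsic CAR / Besag (`icar`) for spatial effects over an
#' adjacency graph, and exchangeable (`iid`) random effects.
#'
#' @name penalty_block
#' @return a list of class `penalty_block` with elements `kind`, `K`
#'   (symmetric positive semi-definite structure matrix), `rank`,
#'   `constraint` (matrix whose rows span the null space of K, i.e. the
#'   directions removed for identifiability), `labels` (grid values or
#'   region names) and `components` (for `icar`).
NULL

new_penalty_block <- function(kind, K, rank, constraint, labels,
                              components = NULL) {
  structure(list(kind = kind, K = K, rank = rank, constraint = constraint,
                 labels = labels, components = components),
            class = "penalty_block")
}

#' @export
print.penalty_block <- function(x, ...) {
  cat(sprintf("Penalty block [%s]: dim %d, rank %d, null space %d\n",
              x$kind, nrow(x$K), x$rank, nrow(x$K) - x$rank))
  invisible(x)
}

#' Second-order random walk precision structure
#'
#' Builds \eqn{K = D_2^\top D_2} where \eqn{D_2} is the
#' \eqn{(m-2) \times m} second-difference operator on an equispaced grid.
#' The quadratic form \eqn{f^\top K f} equals the sum of squared second
#' differences of `f`, so the prior penalises curvature; its null space
#' contains constants and linear trends (rank `m - 2`).
#'
#' @param grid sorted numeric grid values, or a single integer giving the
#'   grid size `m >= 3`.
#' @return a [penalty_block] of kind `"rw2"`.
#' @examples
#' rw2_precision(3)$K  # rbind(c(1,-2,1), c(-2,4,-2), c(1,-2,1))
#' @export
rw2_precision <- function(grid) {
  if (length(grid) == 1L && grid == as.integer(grid)) {
    m <- as.integer(grid)
    grid <- seq_len(m)
  } else {
    grid <- sort(unique(as.numeric(grid)))
    m <- length(grid)
  }
  if (m < 3L) stop("an RW2 penalty needs a grid of at least 3 values")
  D2 <- matrix(0, m - 2L, m)
  for (i in seq_len(m - 2L)) D2[i, i:(i + 2L)] <- c(1, -2, 1)
  K <- crossprod(D2)
  constraint <- rbind(rep(1, m), grid)
  new_penalty_block("rw2", K, rank = m - 2L, constraint = constraint,
                    labels = grid)
}

#' Intrinsic CAR (Besag) precision structure
#'
#' Builds the unweighted intrinsic conditional autoregressive structure
#' matrix \eqn{K = \mathrm{diag}(d) - A} from a binary adjacency graph,
#' where `d` holds the neighbour counts and `A` the adjacency matrix.
#' `K 1 = 0` within every connected component, so the rank is
#' `n - #components` and a sum-to-zero constraint per component is needed
#' for identifiability.
#'
#' @param g an [adjacency_graph()] with at least 2 regions.
#' @return a [penalty_block] of kind `"icar"`.
#' @export
icar_precision <- function(g) {
  stopifnot(inherits(g, "adjacency_graph"))
  n <- n_regions(g)
  if (n < 2L) stop("an ICAR prior needs at least 2 regions")
  K <- matrix(0, n, n, dimnames = list(g$labels, g$labels))
  for (i in seq_len(n)) {
    nb <- match(g$neighbors[[g$labels[i]]], g$labels)
    K[i, nb] <- -1
    K[i, i] <- length(nb)
  }
  ncomp <- max(g$components)
  constraint <- matrix(0, ncomp, n, dimnames = list(NULL, g$labels))
  for (k in seq_len(ncomp)) constraint[k, g$components == k] <- 1
  new_penalty_block("icar", K, rank = n - ncomp, constraint = constraint,
                    labels = g$labels, components = unname(g$components))
}

#' Exchangeable (iid) random-effect structure
#'
#' Identity structure matrix for an unstructured random effect; full rank,
#' no constraint.
#'
#' @param labels level labels of the grouping factor.
#' @return a [penalty_block] of kind `"iid"`.
#' @export
iid_precision <- function(labels) {
  labels <- as.character(labels)
  m <- length(labels)
  if (m < 1L) stop("empty label set")
  K <- diag(m)
  dimnames(K) <- list(labels, labels)
  new_penalty_block("iid", K, rank = m,
                    constraint = matrix(numeric(0), 0, m), labels = labels)
}

#' Export a precision structure as sparse coordinate text
#'
#' Writes the non-zero entries of a [penalty_block] structure matrix as
#' `row<TAB>col<TAB>value` lines.
#'
#' @param block a [penalty_block].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_precision <- function(block, path) {
  stopifnot(inherits(block, "penalty_block"))
  K <- block$K
  idx <- which(K != 0, arr.ind = TRUE)
  lines <- sprintf("%d\t%d\t%.17g", idx[, 1], idx[, 2], K[idx])
  writeLines(lines, path)
  invisible(path)
}
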