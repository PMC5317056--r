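#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler Q criterion.
#' Deterministic: on equal Q values the pair with the lowest row/column
#' indices is joined. With three taxa the unique unrooted topology with
#' the closed-form three-point branch lengths is returned. Negative
#' branch-length estimates are kept as computed (they preserve additivity
#' of path lengths).
#'
#' @param d A symmetric distance matrix (or `dist`) with complete
#'   entries; row names become tip labels.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need >= 3 taxa", call. = FALSE)
  if (anyNA(d)) stop("distance matrix has missing entries", call. = FALSE)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  labels <- rownames(d)
  # each active element carries its newick subtree string
  nwk <- labels
  D <- d
  while (length(nwk) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest-index pair on ties: scan column-major over upper triangle
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    k <- which(Q == min(Q), arr.ind = TRUE)
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]
    i <- k[1]; j <- k[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    merged <- sprintf("(%s:%.15g,%s:%.15g)", nwk[i], bi, nwk[j], bj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    nwk <- c(nwk[keep], merged)
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 nwk[1], b1, nwk[2], b2, nwk[3], b3)
  ape::read.tree(text = txt)
}
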