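#' Genome-wide simple-matching distance matrix
#'
#' One minus the simple matching coefficient over all sites,
#' pairwise-complete in the presence of missing genotypes.
#'
#' @param x A `cotton_geno` (>= 2 accessions).
#' @return Accession-by-accession distance matrix (values in `[0, 1]`,
#'   zero diagonal; `NA` for pairs without jointly called sites).
#' @export
genomewide_distance <- function(x) {
  if (n_accessions(x) < 2) stop("need >= 2 accessions", call. = FALSE)
  simple_matching(x$calls)
}

#' Genome-wide NJ tree
#'
#' [nj_tree()] on the genome-wide simple-matching distances.
#'
#' @param x A `cotton_geno` or a distance matrix.
#' @return An unrooted `phylo`.
#' @export
build_tree <- function(x) {
  d <- if (inherits(x, "cotton_geno")) genomewide_distance(x) else as.matrix(x)
  if (anyNA(d)) stop("distance matrix has missing entries", call. = FALSE)
  nj_tree(d)
}

#' Principal component analysis of genotypes
#'
#' EIGENSTRAT-style PCA: each site column is centred by twice its allele
#' frequency and scaled by `sqrt(p(1-p))` (Patterson normalisation);
#' missing entries are mean-imputed (zero after centring); the accession
#' covariance matrix is eigendecomposed. The sign of each component is
#' fixed so that its largest-magnitude loading is positive.
#'
#' @param x A `cotton_geno` (>= 2 accessions, >= 2 SNPs).
#' @param n_components Number of components to return (default 10).
#' @return List of class `cotton_pca`: `scores` (tibble with `id` and
#'   `PC1..PCk`, joined with the panel), `eigenvalues` (nonincreasing,
#'   nonnegative up to numerical noise), `var_explained`.
#' @export
pca_genotypes <- function(x, n_components = 10) {
  if (n_accessions(x) < 2 || n_sites(x) < 2) {
    stop("need >= 2 accessions and >= 2 sites", call. = FALSE)
  }
  g <- x$calls
  p <- colMeans(g, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (!any(keep)) stop("all sites monomorphic or missing", call. = FALSE)
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  z <- sweep(g, 2, 2 * p)
  z <- sweep(z, 2, sqrt(p * (1 - p)), "/")
  z[is.na(z)] <- 0
  cov <- z %*% t(z) / ncol(z)
  eig <- eigen(cov, symmetric = TRUE)
  k <- min(n_components, ncol(eig$vectors))
  vec <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    big <- which.max(abs(vec[, j]))
    if (vec[big, j] < 0) vec[, j] <- -vec[, j]
  }
  colnames(vec) <- paste0("PC", seq_len(k))
  scores <- dplyr::bind_cols(x$panel, tibble::as_tibble(vec))
  structure(list(scores = scores, eigenvalues = eig$values,
                 var_explained = eig$values[seq_len(k)] /
                   sum(pmax(eig$values, 0))),
            class = "cotton_pca")
}

#' @export
print.cotton_pca <- function(x, ...) {
  cat("<cotton_pca> ", nrow(x$scores), " accessions; PC1 ",
      signif(100 * x$var_explained[1], 3), "% of variance\n", sep = "")
  invisible(x)
}
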