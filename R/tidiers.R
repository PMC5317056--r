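#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an f3 result
#'
#' @param x An `f3_result`.
#' @param ... Unused.
#' @return Tibble with `estimate`, `std.error`, `statistic` (the Z
#'   score).
#' @export
tidy.f3_result <- function(x, ...) {
  tibble::tibble(term = "f3", estimate = x$f3, std.error = x$se,
                 statistic = x$z)
}

#' @rdname tidy.f3_result
#' @export
glance.f3_result <- function(x, ...) {
  tibble::tibble(n_sites = x$n_sites_used, n_blocks = x$n_blocks)
}

#' Tidy a PCA of genotypes
#'
#' @param x A `cotton_pca`.
#' @param ... Unused.
#' @return The score tibble (accession metadata plus PC coordinates).
#' @export
tidy.cotton_pca <- function(x, ...) x$scores

#' @rdname tidy.cotton_pca
#' @export
glance.cotton_pca <- function(x, ...) {
  tibble::tibble(n_accessions = nrow(x$scores),
                 pc1_var = x$var_explained[1],
                 pc2_var = x$var_explained[2])
}
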