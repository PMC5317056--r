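# Per-site unbiased heterozygosity 2*p*(1-p)*n/(n-1) for one population,
# with n the called allele count. Sites with n < 2 contribute NA.
site_heterozygosity <- function(x, ids) {
  f <- site_frequencies(x, ids)
  ifelse(f$n_called >= 2,
         2 * f$freq * (1 - f$freq) * f$n_called / (f$n_called - 1),
         NA_real_)
}

# Map each site to its window row index (0-based half-open windows,
# 1-based positions), NA when outside every window.
site_window_index <- function(x, windows) {
  idx <- rep(NA_integer_, n_sites(x))
  for (w in seq_len(nrow(windows))) {
    hit <- x$sites$chrom == windows$chrom[w] &
      x$sites$pos > windows$start[w] & x$sites$pos <= windows$end[w]
    idx[hit] <- w
  }
  idx
}

#' Windowed nucleotide diversity (pi)
#'
#' Per window, pi is the sum over variant sites of the unbiased per-site
#' heterozygosity `2*p*(1-p)*n/(n-1)` (p the population alternate-allele
#' frequency, n the called allele count) divided by the full window
#' length in bp; positions without a variant record are treated as
#' monomorphic. Windows where no site has two called alleles and at least
#' one site exists are flagged undefined.
#'
#' @param x A `cotton_geno`.
#' @param ids Accession ids of the population (>= 2 accessions).
#' @param windows Window tibble (`chrom`, `start`, `end`), e.g. from
#'   [tile_genome()].
#' @return Tibble: windows plus `pi`, `n_snps`, `undefined`.
#' @export
window_pi <- function(x, ids, windows) {
  if (length(ids) < 2) stop("population needs >= 2 accessions", call. = FALSE)
  het <- site_heterozygosity(x, ids)
  wi <- site_window_index(x, windows)
  n_w <- nrow(windows)
  sums <- rep(0, n_w); n_snps <- rep(0L, n_w); n_usable <- rep(0L, n_w)
  ok <- !is.na(wi)
  if (any(ok)) {
    n_snps <- as.integer(tabulate(wi[ok], nbins = n_w))
    usable <- ok & !is.na(het)
    n_usable <- as.integer(tabulate(wi[usable], nbins = n_w))
    if (any(usable)) {
      agg <- rowsum(het[usable], wi[usable], reorder = TRUE)
      sums[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  dplyr::mutate(tibble::as_tibble(windows),
                pi = sums / (windows$end - windows$start),
                n_snps = n_snps,
                undefined = n_snps > 0 & n_usable == 0)
}

#' Windowed Hudson F_ST
#'
#' Hudson's two-population estimator, windowed as a ratio of sums: per
#' site the numerator is `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`
#' and the denominator `p1(1-p2) + p2(1-p1)` (allele counts n1, n2);
#' window F_ST is the summed numerator over the summed denominator.
#' Robust to unequal sample sizes; equals 1 only under reciprocal
#' fixation.
#'
#' @param x A `cotton_geno`.
#' @param ids_a,ids_b Accession ids of the two populations (>= 2 each).
#' @param windows Window tibble, or `NULL` for a single genome-wide
#'   estimate.
#' @return Tibble with `fst`, `n_sites_used`, `undefined` per window (one
#'   row, `chrom = NA`, when `windows` is `NULL`).
#' @export
window_fst <- function(x, ids_a, ids_b, windows = NULL) {
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    stop("both populations need >= 2 accessions", call. = FALSE)
  }
  fa <- site_frequencies(x, ids_a)
  fb <- site_frequencies(x, ids_b)
  ok <- fa$n_called >= 2 & fb$n_called >= 2
  p1 <- fa$freq; p2 <- fb$freq; n1 <- fa$n_called; n2 <- fb$n_called
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num[!ok] <- NA; den[!ok] <- NA
  if (is.null(windows)) {
    d <- sum(den, na.rm = TRUE)
    return(tibble::tibble(chrom = NA_character_, start = NA_real_,
                          end = NA_real_,
                          fst = if (d > 0) sum(num, na.rm = TRUE) / d else NA_real_,
                          n_sites_used = sum(ok & den > 0, na.rm = TRUE),
                          undefined = !(d > 0)))
  }
  wi <- site_window_index(x, windows)
  use <- !is.na(wi) & ok & !is.na(den)
  n_w <- nrow(windows)
  num_s <- den_s <- rep(0, n_w); n_used <- rep(0L, n_w)
  if (any(use)) {
    agg <- rowsum(cbind(num[use], den[use]), wi[use], reorder = TRUE)
    rows <- as.integer(rownames(agg))
    num_s[rows] <- agg[, 1]; den_s[rows] <- agg[, 2]
    n_used <- as.integer(tabulate(wi[use], nbins = n_w))
  }
  dplyr::mutate(tibble::as_tibble(windows),
                fst = ifelse(den_s > 0, num_s / den_s, NA_real_),
                n_sites_used = n_used,
                undefined = !(den_s > 0))
}
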