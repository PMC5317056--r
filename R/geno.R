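#' Genotype matrix container
#'
#' Holds a panel of accessions genotyped at an ordered set of biallelic
#' sites. Calls are diploid-coded alternate-allele counts (0, 1, 2) with
#' `NA` for missing genotypes; tetraploidy is represented by the two
#' subgenomes' separate chromosomes, not by four-allele genotypes, because
#' reads are assigned to one subgenome before calling.
#'
#' @param calls Integer matrix, accessions (rows, named by accession id) by
#'   sites (columns); values in `{0, 1, 2, NA}`.
#' @param sites Tibble with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt`, `vtype` (`"snp"`/`"indel"`), `indel_length` (signed bp, 0 for
#'   SNPs); must be sorted by (`chrom`, `pos`).
#' @param panel Accession panel tibble (see [accession_panel()]); ids must
#'   match `rownames(calls)`.
#' @return An object of class `cotton_geno`.
#' @export
geno_matrix <- function(calls, sites, panel) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  sites <- tibble::as_tibble(sites)
  need <- c("chrom", "pos", "ref", "alt", "vtype", "indel_length")
  stopifnot(all(need %in% names(sites)))
  if (nrow(sites) != ncol(calls)) {
    stop("sites and call columns disagree", call. = FALSE)
  }
  if (nrow(panel) != nrow(calls)) {
    stop("panel and call rows disagree", call. = FALSE)
  }
  if (is.null(rownames(calls))) rownames(calls) <- panel$id
  if (!identical(rownames(calls), panel$id)) {
    stop("call row names must match panel ids, in order", call. = FALSE)
  }
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("calls must be 0, 1, 2 or NA", call. = FALSE)
  o <- order(sites$chrom, sites$pos)
  if (!identical(o, seq_len(nrow(sites)))) {
    sites <- sites[o, , drop = FALSE]
    calls <- calls[, o, drop = FALSE]
  }
  structure(list(calls = calls, sites = sites, panel = panel),
            class = "cotton_geno")
}

#' @export
print.cotton_geno <- function(x, ...) {
  cat("<cotton_geno> ", nrow(x$panel), " accessions x ", nrow(x$sites),
      " sites (", sum(x$sites$vtype == "snp"), " SNP, ",
      sum(x$sites$vtype == "indel"), " indel); missing rate ",
      signif(mean(is.na(x$calls)), 3), "\n", sep = "")
  invisible(x)
}

#' Number of sites / accessions
#' @param x A `cotton_geno`.
#' @return Integer count.
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname n_sites
#' @export
n_accessions <- function(x) nrow(x$panel)

#' Subset a genotype matrix by site index or by accession id
#'
#' @param x A `cotton_geno`.
#' @param sites Integer or logical index into the site list (optional).
#' @param ids Character vector of accession ids to keep (optional).
#' @return A `cotton_geno` restricted to the selection.
#' @export
geno_subset <- function(x, sites = NULL, ids = NULL) {
  calls <- x$calls
  st <- x$sites
  panel <- x$panel
  if (!is.null(sites)) {
    calls <- calls[, sites, drop = FALSE]
    st <- st[sites, , drop = FALSE]
  }
  if (!is.null(ids)) {
    m <- match(ids, panel$id)
    if (anyNA(m)) stop("unknown accession ids", call. = FALSE)
    calls <- calls[m, , drop = FALSE]
    panel <- panel[m, , drop = FALSE]
  }
  geno_matrix(calls, st, panel)
}

#' Per-site alternate-allele frequency and called-allele count
#'
#' Frequency is the alternate-allele count divided by the number of called
#' alleles (missing genotypes are excluded from the denominator); sites
#' where a population has no calls get `NA` frequency.
#'
#' @param x A `cotton_geno`.
#' @param ids Accession ids defining the population (default: all).
#' @return Tibble with columns `chrom`, `pos`, `freq`, `n_called`
#'   (called allele count, i.e. 2 x called genotypes).
#' @export
site_frequencies <- function(x, ids = NULL) {
  calls <- if (is.null(ids)) x$calls else {
    m <- match(ids, x$panel$id)
    if (anyNA(m)) stop("unknown accession ids", call. = FALSE)
    x$calls[m, , drop = FALSE]
  }
  n_called <- 2L * colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)
  tibble::tibble(
    chrom = x$sites$chrom, pos = x$sites$pos,
    freq = ifelse(n_called > 0, alt / n_called, NA_real_),
    n_called = n_called
  )
}

#' Logical index of sites inside a set of intervals
#'
#' Intervals are 0-based half-open; site positions are 1-based, so position
#' `pos` lies in `[start, end)` iff `start < pos <= end`.
#'
#' @param x A `cotton_geno`.
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @return Logical vector over sites.
#' @export
sites_in_intervals <- function(x, intervals) {
  hit <- rep(FALSE, nrow(x$sites))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (x$sites$chrom == intervals$chrom[i] &
                    x$sites$pos > intervals$start[i] &
                    x$sites$pos <= intervals$end[i])
  }
  hit
}
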