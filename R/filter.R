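#' Drop singleton variants
#'
#' Keeps sites where the alternate allele is present (genotype call of 1
#' or 2) in at least `min_accessions` accessions. The filter cascade used
#' throughout the package is non-singleton, then MAF/missing, then
#' spacing; each step only removes sites.
#'
#' @param x A `cotton_geno`.
#' @param min_accessions Minimum number of alt-carrying accessions
#'   (default 2).
#' @return The filtered `cotton_geno`.
#' @export
nonsingleton_filter <- function(x, min_accessions = 2) {
  carriers <- colSums(x$calls >= 1L, na.rm = TRUE)
  geno_subset(x, sites = carriers >= min_accessions)
}

#' Minor-allele-frequency and missing-rate filter
#'
#' Keeps sites whose minor allele frequency exceeds `maf` and whose
#' missing genotype fraction is below `miss`, both computed over all
#' accessions (missing calls excluded from the frequency denominator).
#'
#' @param x A `cotton_geno`.
#' @param maf MAF threshold (strict `>`; default 0.05).
#' @param miss Missing-rate threshold (strict `<`; default 0.10).
#' @return The filtered `cotton_geno`.
#' @export
maf_missing_filter <- function(x, maf = 0.05, miss = 0.10) {
  f <- site_frequencies(x)
  minor <- pmin(f$freq, 1 - f$freq)
  missing_rate <- colMeans(is.na(x$calls))
  keep <- !is.na(minor) & minor > maf & missing_rate < miss
  geno_subset(x, sites = keep)
}

#' Spacing filter: thin sites closer than a minimum gap
#'
#' Homoeologous mis-mapping inflates SNP density locally; clustered
#' polymorphic sites are therefore thinned until all surviving sites on a
#' chromosome are at least `min_gap` bp apart. Conflicts are resolved by
#' repeatedly taking the closest conflicting pair and removing one of its
#' two members uniformly at random, reproducibly from `seed`.
#'
#' @param x A `cotton_geno`.
#' @param min_gap Minimum spacing in bp (default 10).
#' @param seed Integer seed for the random removals.
#' @return The filtered `cotton_geno`.
#' @export
spacing_filter <- function(x, min_gap = 10, seed = 1L) {
  with_seed(seed, {
    keep_global <- logical(0)
    for (ch in unique(x$sites$chrom)) {
      idx <- which(x$sites$chrom == ch)
      pos <- x$sites$pos[idx]
      alive <- rep(TRUE, length(pos))
      if (length(pos) >= 2) {
        # conflicts are confined to maximal runs of close sites: removals
        # inside a run never create a conflict across its boundary
        run_id <- cumsum(c(TRUE, diff(pos) >= min_gap))
        for (run in split(seq_along(pos), run_id)) {
          if (length(run) < 2) next
          sub_alive <- rep(TRUE, length(run))
          repeat {
            ap <- pos[run][sub_alive]
            if (length(ap) < 2) break
            gaps <- diff(ap)
            if (all(gaps >= min_gap)) break
            k <- which.min(gaps)  # first closest conflicting pair
            victim <- if (stats::runif(1) < 0.5) k else k + 1L
            sub_alive[which(sub_alive)[victim]] <- FALSE
          }
          alive[run] <- sub_alive
        }
      }
      keep_global <- c(keep_global, alive)
    }
    # chromosomes iterated in site order, so keep_global aligns with sites
    stopifnot(length(keep_global) == n_sites(x))
    geno_subset(x, sites = keep_global)
  })
}

#' Classify SNPs as intraspecific or nearly fixed interspecific
#'
#' A site is *nearly fixed interspecific* when its alternate-allele
#' frequency exceeds `fix_hi` in one species and falls below `fix_lo` in
#' the other; it is *intraspecific* in a species when its within-species
#' minor allele frequency exceeds `1 - fix_hi` (5% under the defaults,
#' mirroring the common-SNP MAF rule). The two intraspecific labels are
#' not exclusive; a site undefined in either species (no called alleles)
#' is flagged.
#'
#' @param x A `cotton_geno`.
#' @param fix_hi,fix_lo Fixation thresholds (defaults 0.95 / 0.05).
#' @return Tibble with `chrom`, `pos`, `freq_hirsutum`, `freq_barbadense`,
#'   logical `intraspecific_hirsutum`, `intraspecific_barbadense`,
#'   `nearly_fixed_interspecific`, `undefined`, and a summary `category`
#'   column (`nearly_fixed_interspecific` > `intraspecific_*` > `other`).
#' @export
classify_snp_categories <- function(x, fix_hi = 0.95, fix_lo = 0.05) {
  f_h <- site_frequencies(x, panel_ids(x$panel, species = "hirsutum"))
  f_b <- site_frequencies(x, panel_ids(x$panel, species = "barbadense"))
  maf_h <- pmin(f_h$freq, 1 - f_h$freq)
  maf_b <- pmin(f_b$freq, 1 - f_b$freq)
  undefined <- is.na(f_h$freq) | is.na(f_b$freq)
  nearly <- !undefined &
    ((f_h$freq > fix_hi & f_b$freq < fix_lo) |
       (f_b$freq > fix_hi & f_h$freq < fix_lo))
  intra_h <- !is.na(maf_h) & maf_h > (1 - fix_hi)
  intra_b <- !is.na(maf_b) & maf_b > (1 - fix_hi)
  tibble::tibble(
    chrom = x$sites$chrom, pos = x$sites$pos,
    freq_hirsutum = f_h$freq, freq_barbadense = f_b$freq,
    intraspecific_hirsutum = intra_h,
    intraspecific_barbadense = intra_b,
    nearly_fixed_interspecific = nearly,
    undefined = undefined,
    category = dplyr::case_when(
      undefined ~ "undefined",
      nearly ~ "nearly_fixed_interspecific",
      intra_h & intra_b ~ "intraspecific_both",
      intra_h ~ "intraspecific_hirsutum",
      intra_b ~ "intraspecific_barbadense",
      TRUE ~ "other"
    )
  )
}

#' Summarise SNP category counts
#'
#' @param categories Output of [classify_snp_categories()], or a named
#'   count vector/tibble with columns `category` and `n`.
#' @return Tibble with `category`, `n` and `pct` (share of classified
#'   sites, in percent).
#' @export
summarize_snp_categories <- function(categories) {
  counts <- if (is.data.frame(categories) && "category" %in% names(categories) &&
                !"n" %in% names(categories)) {
    dplyr::count(categories, .data$category)
  } else tibble::as_tibble(categories)
  total <- sum(counts$n[counts$category != "undefined"])
  dplyr::mutate(counts, pct = 100 * .data$n / total)
}
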