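# NG86 site counts for one codon: the fraction of the 9 single-base
# mutations that are nonsynonymous (stop-gained counted as nonsynonymous),
# times 3; synonymous sites are the complement.
codon_site_counts <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa0 <- translate_codon(codon)
  n_syn <- 0L; n_total <- 0L
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (b in setdiff(bases, ref)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      n_total <- n_total + 1L
      if (translate_codon(mut) == aa0) n_syn <- n_syn + 1L
    }
  }
  syn <- 3 * n_syn / n_total
  c(syn = syn, nonsyn = 3 - syn)
}

# Precomputed NG86 site counts for all 64 codons.
ng86_table <- function() {
  t(vapply(names(GENETIC_CODE_DNA), codon_site_counts, numeric(2)))
}

#' Ka/Ks ratio from classified coding SNPs (NG86 site counting)
#'
#' Counts nonsynonymous (including stop-gained) and synonymous SNPs over a
#' gene set and normalises each by the NG86 nonsynonymous/synonymous site
#' counts of the genes' CDS: `ratio = (N / N_sites) / (S / S_sites)`.
#' This is a count ratio over SNP classes, not a divergence model (no
#' multiple-hit correction).
#'
#' @param effects Effect tibble from [annotate_coding_effects()].
#' @param models Gene-model tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param gene_set Character vector of gene ids (default: all models).
#' @return One-row tibble: `n_nonsyn`, `n_syn`, `nonsyn_sites`,
#'   `syn_sites`, `ka`, `ks`, `ratio` (`NA` with `undefined = TRUE` when
#'   no synonymous SNPs or sites).
#' @export
kaks_ratio <- function(effects, models, genome, gene_set = NULL) {
  if (is.null(gene_set)) gene_set <- models$gene_id
  if (length(gene_set) == 0) stop("empty gene set", call. = FALSE)
  tab <- ng86_table()
  syn_sites <- 0; nonsyn_sites <- 0
  for (i in which(models$gene_id %in% gene_set)) {
    orf <- cds_sequence(models[i, ], genome)
    n_cod <- nchar(orf) %/% 3L
    cods <- substring(orf, 3L * (seq_len(n_cod) - 1L) + 1L,
                      3L * seq_len(n_cod))
    cods <- cods[nchar(cods) == 3L & !grepl("[^ACGT]", cods)]
    syn_sites <- syn_sites + sum(tab[cods, "syn"])
    nonsyn_sites <- nonsyn_sites + sum(tab[cods, "nonsyn"])
  }
  e <- effects[!is.na(effects$gene_id) & effects$gene_id %in% gene_set, ]
  n_nonsyn <- sum(e$effect %in% c("nonsynonymous", "stop_gained"))
  n_syn <- sum(e$effect == "synonymous")
  ka <- if (nonsyn_sites > 0) n_nonsyn / nonsyn_sites else NA_real_
  ks <- if (syn_sites > 0) n_syn / syn_sites else NA_real_
  undefined <- is.na(ks) || ks == 0
  tibble::tibble(n_nonsyn = n_nonsyn, n_syn = n_syn,
                 nonsyn_sites = nonsyn_sites, syn_sites = syn_sites,
                 ka = ka, ks = ks,
                 ratio = if (undefined) NA_real_ else ka / ks,
                 undefined = undefined)
}

#' Linkage-disequilibrium decay profile
#'
#' Squared composite genotype correlation (r^2, unphased) for all
#' intra-chromosomal site pairs within `max_dist` bp, binned by physical
#' distance; missing genotypes are handled pairwise-complete.
#'
#' @param x A `cotton_geno`.
#' @param ids Accession ids of the population.
#' @param max_dist Maximum pair distance in bp.
#' @param breaks Distance-bin breakpoints in bp (default 10 log-spaced
#'   bins from 1 to `max_dist`).
#' @return Tibble: `bin_lo`, `bin_hi`, `mean_r2`, `n_pairs` (empty bins
#'   flagged by `n_pairs = 0`, `mean_r2 = NA`).
#' @export
ld_decay <- function(x, ids, max_dist = 1e6, breaks = NULL) {
  if (is.null(breaks)) {
    breaks <- unique(c(0, round(exp(seq(log(1000), log(max_dist),
                                        length.out = 10)))))
  }
  g <- x$calls[match(ids, x$panel$id), , drop = FALSE]
  nb <- length(breaks) - 1L
  sums <- rep(0, nb); counts <- rep(0L, nb)
  for (ch in unique(x$sites$chrom)) {
    idx <- which(x$sites$chrom == ch)
    if (length(idx) < 2) next
    pos <- x$sites$pos[idx]
    sub <- g[, idx, drop = FALSE]
    # pairwise-complete r^2 from cross-products of the observed entries
    obs <- !is.na(sub); mode(obs) <- "numeric"
    xz <- sub; xz[is.na(xz)] <- 0
    n <- crossprod(obs)
    sx <- crossprod(xz, obs)            # sum of x over jointly observed
    sxx <- crossprod(xz^2, obs)
    sxy <- crossprod(xz)
    num <- n * sxy - sx * t(sx)
    den <- (n * sxx - sx^2) * t(n * sxx - sx^2)
    r2 <- ifelse(den > 0, num^2 / den, NA_real_)
    dmat <- abs(outer(pos, pos, "-"))
    up <- upper.tri(r2)
    ok <- up & dmat <= max_dist & !is.na(r2) & n >= 2
    if (!any(ok)) next
    bin <- findInterval(dmat[ok], breaks, left.open = TRUE)
    inb <- bin >= 1 & bin <= nb
    if (!any(inb)) next
    agg <- rowsum(r2[ok][inb], bin[inb], reorder = TRUE)
    sums[as.integer(rownames(agg))] <-
      sums[as.integer(rownames(agg))] + agg[, 1]
    counts <- counts + tabulate(bin[inb], nbins = nb)
  }
  tibble::tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                 mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
                 n_pairs = counts)
}
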