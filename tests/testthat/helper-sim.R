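# Shared fixture builders. Everything is generated in code; the small
# layout keeps unit tests fast while the acceptance tests use the
# package's default desk-scale configuration.

tiny_layout <- function(len = 2e5) {
  genome_layout(
    tibble::tibble(chrom = c("A01", "A02", "D01", "D02"), length = len,
                   subgenome = c("A", "A", "D", "D")),
    tibble::tibble(a_chrom = c("A01", "A02"), a_start = 0, a_end = len,
                   d_chrom = c("D01", "D02"), d_start = 0, d_end = len)
  )
}

tiny_config <- function(seed = 1L, ...) {
  sim_config(layout = tiny_layout(), seed = seed, ...)
}

# Hand-built genotype matrix: calls is accessions x sites, positions on
# one chromosome unless chrom given.
make_geno <- function(calls, pos = NULL, chrom = "A01",
                      species = NULL, group = NULL) {
  n_acc <- nrow(calls); n_s <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(n_s) * 100L
  if (is.null(species)) species <- rep("hirsutum", n_acc)
  if (is.null(group)) group <- rep("cultivar", n_acc)
  ids <- sprintf("acc%02d", seq_len(n_acc))
  rownames(calls) <- ids
  geno_matrix(
    calls,
    tibble::tibble(chrom = rep(chrom, length.out = n_s), pos = pos,
                   ref = "A", alt = "T", vtype = "snp", indel_length = 0L),
    accession_panel(ids, species, group)
  )
}

# Redraw the hirsutum cultivars as a 50/50 frequency mixture of the race
# and barbadense truth frequencies (frequency-level admixture).
mix_cultivars <- function(g, seed = 1L) {
  truth <- attr(g, "truth")
  mix <- (truth$freqs$race + truth$freqs$barbadense) / 2
  rows <- which(g$panel$species == "hirsutum" & g$panel$group == "cultivar")
  cottonpop:::with_seed(seed, {
    g$calls[rows, ] <- matrix(
      stats::rbinom(length(rows) * n_sites(g), 2,
                    rep(mix, each = length(rows))), nrow = length(rows))
    g
  })
}

# Brute-force mean pairwise allele difference per site, averaged over a
# window: the classical pi estimator, independent of the package's
# frequency-based formula.
oracle_window_pi <- function(calls, window_length) {
  total <- 0
  for (s in seq_len(ncol(calls))) {
    alleles <- unlist(lapply(calls[, s], function(g) {
      if (is.na(g)) NULL else c(rep(1, g), rep(0, 2 - g))
    }))
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0
    for (i in seq_len(n - 1)) diffs <- diffs + sum(alleles[i] != alleles[(i + 1):n])
    total <- total + diffs / choose(n, 2)
  }
  total / window_length
}

# Brute-force simple-matching distance for one accession pair.
oracle_sm_distance <- function(a, b) {
  joint <- !is.na(a) & !is.na(b)
  if (!any(joint)) return(NA_real_)
  1 - sum(a[joint] == b[joint]) / sum(joint)
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration (sum of point probabilities <= observed).
oracle_fisher2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(r1 + r2, c1))
  }, numeric(1))
  p_obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
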