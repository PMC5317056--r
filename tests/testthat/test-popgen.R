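test_that("window pi matches the hand-evaluated unbiased formula", {
  # one SNP, alt frequency 0.5 over 10 diploid accessions (n = 20
  # alleles), 100-kb window: pi = 2*0.5*0.5*(20/19)/1e5
  calls <- cbind(c(rep(0L, 5), rep(2L, 5)))
  g <- make_geno(calls, pos = 50L)
  win <- tibble::tibble(chrom = "A01", start = 0, end = 1e5)
  res <- window_pi(g, g$panel$id, win)
  expect_equal(res$pi, (0.5 * 20 / 19) / 1e5, tolerance = 1e-12)

  # monomorphic window
  g0 <- make_geno(cbind(rep(0L, 10)), pos = 50L)
  expect_equal(window_pi(g0, g0$panel$id, win)$pi, 0)
})

test_that("window pi equals the mean-pairwise-difference oracle", {
  set.seed(17)
  for (rep in 1:20) {
    n_acc <- sample(4:12, 1); n_s <- sample(3:15, 1)
    calls <- matrix(sample(c(0:2, NA), n_acc * n_s, replace = TRUE,
                           prob = c(.4, .3, .2, .1)), nrow = n_acc)
    g <- make_geno(calls, pos = sort(sample.int(9999, n_s)))
    win <- tibble::tibble(chrom = "A01", start = 0, end = 1e4)
    expect_equal(window_pi(g, g$panel$id, win)$pi,
                 oracle_window_pi(calls, 1e4), tolerance = 1e-12)
  }
})

test_that("pi is invariant to permuting accessions within the population", {
  g <- geno_subset(simulate_genotypes(tiny_config(seed = 3)), sites = 1:500)
  win <- tibble::tibble(chrom = "A01", start = 0, end = 2e5)
  ids <- panel_ids(g$panel, species = "hirsutum")
  expect_equal(window_pi(g, ids, win)$pi,
               window_pi(g, sample(ids), win)$pi)
})

test_that("Hudson F_ST hits 1 under reciprocal fixation and ~0 under identity", {
  calls <- rbind(matrix(2L, 4, 5), matrix(0L, 4, 5))
  g <- make_geno(calls, species = rep(c("hirsutum", "barbadense"), each = 4),
                 group = rep("cultivar", 8))
  res <- window_fst(g, g$panel$id[1:4], g$panel$id[5:8])
  expect_equal(res$fst, 1)

  null_fst <- vapply(1:10, function(s) {
    set.seed(s)
    p <- runif(300, 0.1, 0.9)
    calls <- matrix(rbinom(20 * 300, 2, rep(p, each = 20)), nrow = 20)
    g <- make_geno(calls, pos = seq_len(300) * 30L)
    window_fst(g, g$panel$id[1:10], g$panel$id[11:20])$fst
  }, numeric(1))
  expect_true(all(abs(null_fst) < 0.02))
})

test_that("windowed F_ST equals the brute-force two-population formula", {
  set.seed(23)
  calls <- matrix(sample(c(0:2, NA), 16 * 100, replace = TRUE,
                         prob = c(.4, .3, .2, .1)), nrow = 16)
  g <- make_geno(calls, pos = seq_len(100) * 80L)
  a_ids <- g$panel$id[1:8]; b_ids <- g$panel$id[9:16]
  res <- window_fst(g, a_ids, b_ids,
                    tibble::tibble(chrom = "A01", start = 0, end = 8000))
  # site-by-site oracle
  num <- den <- 0
  for (s in 1:100) {
    ga <- calls[1:8, s]; gb <- calls[9:16, s]
    n1 <- 2 * sum(!is.na(ga)); n2 <- 2 * sum(!is.na(gb))
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(ga, na.rm = TRUE) / n1; p2 <- sum(gb, na.rm = TRUE) / n2
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  expect_equal(res$fst, num / den, tolerance = 1e-12)
})

test_that("NG86 codon site counts match exhaustive single-base enumeration", {
  # TTT (Phe): of the 9 mutants only TTC stays Phe -> 1/3 synonymous site
  expect_equal(unname(cottonpop:::codon_site_counts("TTT")),
               c(1 / 3 * 3 / 3, 3 - 1 / 3), tolerance = 1e-12)
  # independent enumeration for every codon
  bases <- c("A", "C", "G", "T")
  code <- cottonpop:::GENETIC_CODE_DNA
  for (codon in sample(names(code), 12)) {
    syn <- 0
    for (p in 1:3) for (b in setdiff(bases, substr(codon, p, p))) {
      mut <- codon; substr(mut, p, p) <- b
      if (code[[mut]] == code[[codon]]) syn <- syn + 1
    }
    expect_equal(unname(cottonpop:::codon_site_counts(codon)["syn"]),
                 3 * syn / 9, tolerance = 1e-12)
  }
})

test_that("Ka/Ks ratio equals the hand computation on planted SNP classes", {
  sim <- simulate_gene_models(tiny_layout(), n_genes = 5, n_variants = 60,
                              seed = 21)
  eff <- annotate_coding_effects(sim$variants, sim$models, sim$genome)
  res <- kaks_ratio(eff, sim$models, sim$genome)
  n_n <- sum(eff$effect %in% c("nonsynonymous", "stop_gained"))
  n_s <- sum(eff$effect == "synonymous")
  tab <- cottonpop:::ng86_table()
  sites <- c(0, 0)
  for (i in seq_len(nrow(sim$models))) {
    orf <- cottonpop:::cds_sequence(sim$models[i, ], sim$genome)
    cods <- substring(orf, seq(1, nchar(orf), 3), seq(3, nchar(orf), 3))
    sites <- sites + c(sum(tab[cods, "syn"]), sum(tab[cods, "nonsyn"]))
  }
  expect_equal(res$ratio, (n_n / sites[2]) / (n_s / sites[1]),
               tolerance = 1e-12)
})

test_that("a gene with only synonymous SNPs gives Ka = 0 and ratio 0", {
  genome <- c(A01 = paste0(strrep("A", 10), "ATGCAATGGTAA", strrep("A", 10)))
  models <- tibble::tibble(
    gene_id = "g1", chrom = "A01", strand = "+", length_ok = TRUE,
    cds = list(tibble::tibble(start = 11L, end = 22L, phase = 0L)))
  effects <- tibble::tibble(chrom = "A01", pos = 16L, gene_id = "g1",
                            effect = "synonymous")
  res <- kaks_ratio(effects, models, genome)
  expect_equal(res$ka, 0)
  expect_equal(res$ratio, 0)
  expect_false(res$undefined)
})

test_that("LD r-squared is 1 for duplicated sites and symmetric", {
  set.seed(3)
  col <- rbinom(20, 2, 0.5)
  calls <- cbind(col, col, rbinom(20, 2, 0.5))
  g <- make_geno(calls, pos = c(100L, 600L, 5000L))
  prof <- ld_decay(g, g$panel$id, max_dist = 1e4, breaks = c(0, 1000, 1e4))
  expect_equal(prof$mean_r2[1], 1, tolerance = 1e-9)  # the duplicated pair

  # site storage order does not matter: the container sorts by position
  shuffled <- make_geno(calls[, c(3, 1, 2)], pos = c(5000L, 100L, 600L))
  prof1 <- ld_decay(g, g$panel$id, max_dist = 1e4, breaks = c(0, 1e4))
  prof2 <- ld_decay(shuffled, shuffled$panel$id, max_dist = 1e4,
                    breaks = c(0, 1e4))
  expect_equal(prof1$mean_r2, prof2$mean_r2)
  expect_equal(prof1$n_pairs, prof2$n_pairs)
})

test_that("unlinked sites show near-zero LD", {
  means <- vapply(1:10, function(s) {
    set.seed(s)
    p <- runif(120, 0.2, 0.8)
    calls <- matrix(rbinom(40 * 120, 2, rep(p, each = 40)), nrow = 40)
    g <- make_geno(calls, pos = sort(sample.int(2e5, 120)))
    prof <- ld_decay(g, g$panel$id, max_dist = 2e5, breaks = c(0, 2e5))
    prof$mean_r2[1]
  }, numeric(1))
  expect_true(all(means < 0.05))
})
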