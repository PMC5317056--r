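test_that("simple-matching block distances follow the matching rule", {
  calls <- rbind(c(0L, 2L, 2L), c(0L, 0L, 2L))
  g <- make_geno(calls)
  blocks <- tibble::tibble(chrom = "A01", start = 0, end = 1e3,
                           label = "b1")
  bd <- block_distances(g, blocks)
  d <- bd$dist[[1]]
  expect_equal(d[1, 2], 1 / 3)   # 2 of 3 states match
  expect_equal(diag(d), c(acc01 = 0, acc02 = 0))

  g2 <- make_geno(rbind(c(1L, 2L, 0L), c(1L, 2L, 0L)))
  expect_equal(block_distances(g2, blocks)$dist[[1]][1, 2], 0)
})

test_that("block distances match brute force and behave as a metric", {
  set.seed(61)
  for (rep in 1:20) {
    n_acc <- sample(4:8, 1); n_s <- sample(5:30, 1)
    calls <- matrix(sample(c(0:2, NA), n_acc * n_s, replace = TRUE,
                           prob = c(.4, .25, .25, .1)), nrow = n_acc)
    g <- make_geno(calls, pos = sort(sample.int(999, n_s)))
    d <- block_distances(g, tibble::tibble(chrom = "A01", start = 0,
                                           end = 1e3, label = "b"))$dist[[1]]
    for (i in seq_len(n_acc - 1)) for (j in (i + 1):n_acc) {
      expect_equal(d[i, j], oracle_sm_distance(calls[i, ], calls[j, ]))
      expect_equal(d[i, j], d[j, i])
    }
  }
  # triangle inequality on complete data
  set.seed(62)
  calls <- matrix(sample(0:2, 6 * 40, replace = TRUE), nrow = 6)
  g <- make_geno(calls, pos = seq_len(40) * 10L)
  d <- cottonpop:::simple_matching(g$calls)
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("pairs without jointly called sites are flagged", {
  calls <- rbind(c(1L, NA), c(NA, 2L), c(0L, 0L))
  g <- make_geno(calls)
  bd <- block_distances(g, tibble::tibble(chrom = "A01", start = 0,
                                          end = 1e3, label = "b"))
  expect_true(is.na(bd$dist[[1]][1, 2]))
  expect_equal(bd$n_missing_pairs, 1L)
})

test_that("clade membership finds misplaced accessions on a hand-built tree", {
  panel <- accession_panel(
    c("h1", "h2", "h3", "b1", "b2", "b3", "out"),
    c(rep("hirsutum", 3), rep("barbadense", 3), "outgroup"),
    c(rep("cultivar", 6), "outgroup"))
  # h3 sits inside the barbadense clade
  tree <- ape::read.tree(text = paste0(
    "((h1:0.1,h2:0.1):0.5,((b1:0.1,b2:0.1):0.05,(b3:0.1,h3:0.1):0.05):0.5,",
    "out:2);"))
  pl <- clade_membership(tree, panel, "out", core_fraction = 0.9)
  expect_equal(pl$accession, "h3")
  expect_equal(pl$placed_in, "barbadense")

  # cleanly separated species produce no placements
  tree2 <- ape::read.tree(text = paste0(
    "((h1:0.1,(h2:0.1,h3:0.1):0.1):0.5,",
    "((b1:0.1,b2:0.1):0.05,b3:0.1):0.5,out:2);"))
  expect_equal(nrow(clade_membership(tree2, panel, "out")), 0)

  expect_error(clade_membership(tree, panel, "missing_taxon"), "outgroup")
})

test_that("planted introgression events are recovered with their direction", {
  recovered <- 0; planted <- 0
  for (s in 1:3) {
    cfg <- tiny_config(seed = s)
    events <- tibble::tibble(
      chrom = c("A01", "D01"), start = c(0, 1e5), end = c(1e5, 2e5),
      donor_species = c("hirsutum", "barbadense"),
      recipients = list(c("barb01", "barb02", "barb03"),
                        c("race01", "race02")))
    g <- plant_introgressions(simulate_genotypes(cfg), events, seed = s)
    f <- maf_missing_filter(nonsingleton_filter(g))
    blocks <- tile_genome(cfg$layout, 1e5)
    pl <- block_placements(f, blocks, panel_ids(g$panel, species = "outgroup"))
    ev <- call_introgression_events(pl, layout = cfg$layout)
    planted <- planted + 2
    hit1 <- any(ev$chrom == "A01" & ev$start == 0 &
                  ev$direction == "Gh_to_Gb" & ev$n_accessions >= 2)
    hit2 <- any(ev$chrom == "D01" & ev$start == 1e5 &
                  ev$direction == "Gb_to_Gh" & ev$n_accessions >= 2)
    recovered <- recovered + hit1 + hit2
    # subgenome tags come from the layout
    if (nrow(ev) > 0) {
      expect_equal(ev$subgenome,
                   subgenome_of(cfg$layout, ev$chrom))
    }
  }
  expect_gte(recovered / planted, 0.9)
})

test_that("event calling groups placements and enforces the support minimum", {
  pl <- tibble::tibble(
    block = c("b1", "b1", "b2"), chrom = c("A01", "A01", "D01"),
    start = c(0, 0, 0), end = c(1e6, 1e6, 1e6),
    accession = c("b1a", "b1b", "h9"),
    species = c("barbadense", "barbadense", "hirsutum"),
    placed_in = c("hirsutum", "hirsutum", "barbadense"))
  ev <- call_introgression_events(pl, min_accessions = 2)
  expect_equal(nrow(ev), 1)          # the single-accession block drops out
  expect_equal(ev$direction, "Gh_to_Gb")
  expect_equal(ev$n_accessions, 2L)

  # brute-force grouping oracle on random placements
  set.seed(71)
  blocks <- sprintf("blk%02d", 1:50)
  rand <- tibble::tibble(
    block = sample(blocks, 200, replace = TRUE),
    chrom = "A01", start = 0, end = 1e6,
    accession = sprintf("acc%03d", 1:200),
    species = sample(c("hirsutum", "barbadense"), 200, replace = TRUE))
  rand$placed_in <- ifelse(rand$species == "hirsutum", "barbadense",
                           "hirsutum")
  ev <- call_introgression_events(rand, min_accessions = 2)
  oracle <- table(paste(rand$block, rand$species))
  expect_equal(nrow(ev), sum(oracle >= 2))
  expect_equal(sum(ev$n_accessions), sum(oracle[oracle >= 2]))
})

test_that("balanced direction counts are not significant; exact test matches enumeration", {
  expect_equal(direction_bias_test(10, 10, method = "fisher")$p_value, 1)
  expect_gt(direction_bias_test(10, 10)$p_value, 0.99)

  # exact-test route vs exhaustive hypergeometric enumeration
  set.seed(81)
  for (rep in 1:100) {
    n1 <- sample(0:20, 1); n2 <- sample(0:20, 1)
    if (n1 + n2 == 0) n1 <- 1
    e <- round((n1 + n2) / 2)
    tab <- rbind(c(n1, n2), c(e, e))
    expect_equal(direction_bias_test(n1, n2, method = "fisher")$p_value,
                 oracle_fisher2x2(tab), tolerance = 1e-9)
  }
  expect_error(direction_bias_test(0, 0), "not both zero")
})

test_that("a planted 50/50 direction mix rarely looks biased", {
  set.seed(91)
  p_vals <- vapply(1:50, function(i) {
    n <- 40
    n1 <- rbinom(1, n, 0.5)
    direction_bias_test(n1, n - n1, method = "fisher")$p_value
  }, numeric(1))
  expect_gte(mean(p_vals > 0.05), 0.9)
})

test_that("planted direction bias is recovered within binomial noise", {
  # plant 2:1 Gh->Gb : Gb->Gh events and recover the ratio
  cfg <- tiny_config(seed = 13)
  events <- tibble::tibble(
    chrom = c("A01", "A02", "D01", "A01", "D02", "D01"),
    start = c(0, 0, 0, 1e5, 0, 1e5),
    end = c(1e5, 1e5, 1e5, 2e5, 1e5, 2e5),
    donor_species = c("hirsutum", "hirsutum", "hirsutum", "hirsutum",
                      "barbadense", "barbadense"),
    recipients = list(c("barb01", "barb02"), c("barb03", "barb04"),
                      c("barb05", "barb06"), c("barb07", "barb08"),
                      c("race01", "race02"), c("race03", "race04")))
  g <- plant_introgressions(simulate_genotypes(cfg), events, seed = 13)
  f <- maf_missing_filter(nonsingleton_filter(g))
  pl <- block_placements(f, tile_genome(cfg$layout, 1e5),
                         panel_ids(g$panel, species = "outgroup"))
  ev <- call_introgression_events(pl, layout = cfg$layout)
  n_ghgb <- sum(ev$direction == "Gh_to_Gb")
  n_gbgh <- sum(ev$direction == "Gb_to_Gh")
  expect_gte(n_ghgb, 3)   # planted 4
  expect_gte(n_gbgh, 1)   # planted 2
  expect_gt(n_ghgb, n_gbgh)
})

test_that("f3 arithmetic matches the hand-computed single-site case", {
  res <- f3_statistic(0.5, 0, 1)
  expect_equal(res$f3, -0.5)
  expect_true(is.na(res$se))
  expect_error(f3_statistic(c(0, 1), c(0, 1), c(0, 1)), "monomorphic")
})

test_that("f3 is positive under pure drift and negative under admixture", {
  pos <- neg <- 0
  for (s in 1:5) {
    g <- simulate_genotypes(tiny_config(seed = s))
    race <- panel_ids(g$panel, species = "hirsutum", group = "race")
    cult <- panel_ids(g$panel, species = "hirsutum", group = "cultivar")
    barb <- panel_ids(g$panel, species = "barbadense")
    outg <- panel_ids(g$panel, species = "outgroup")
    drift <- f3_test(g, barb, race, outg)
    if (drift$f3 > 0) pos <- pos + 1
    mixed <- f3_test(mix_cultivars(g, seed = s), cult, race, barb)
    if (mixed$f3 < 0 && mixed$z < -3) neg <- neg + 1
  }
  expect_equal(pos, 5)
  expect_gte(neg, 4)
})

test_that("f3 results expose broom-style tidiers", {
  g <- simulate_genotypes(tiny_config(seed = 3))
  res <- f3_test(g, panel_ids(g$panel, species = "barbadense"),
                 panel_ids(g$panel, species = "hirsutum", group = "race"),
                 panel_ids(g$panel, species = "outgroup"))
  td <- generics::tidy(res)
  expect_equal(td$estimate, res$f3)
  expect_equal(td$statistic, res$z)
  expect_equal(generics::glance(res)$n_blocks, res$n_blocks)
})
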