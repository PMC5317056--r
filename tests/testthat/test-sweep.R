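make_track <- function(ratio, masked = rep(FALSE, length(ratio)),
                       chrom = rep("A01", length(ratio))) {
  n <- length(ratio)
  start <- unlist(lapply(rle(chrom)$lengths, function(k) (seq_len(k) - 1) * 1e5))
  tibble::tibble(chrom = chrom, start = start, end = start + 1e5,
                 pi_race = NA_real_, pi_cultivar = NA_real_,
                 ratio = ifelse(masked, NA_real_, ratio), masked = masked)
}

test_that("ratio profile divides, masks low-diversity windows and flags zero cultivar pi", {
  win <- tibble::tibble(chrom = "A01", start = c(0, 1e5, 2e5),
                        end = c(1e5, 2e5, 3e5))
  race <- dplyr::mutate(win, pi = c(0.0025, 0.0005, 0.0025),
                        n_snps = 5L, undefined = FALSE)
  cult <- dplyr::mutate(win, pi = c(0.0001, 0.0005, 0),
                        n_snps = 5L, undefined = FALSE)
  tr <- sweep_ratio_profile(race, cult)
  expect_equal(tr$ratio[1], 25)
  expect_true(tr$masked[2])            # < 0.001 in both groups
  expect_true(is.infinite(tr$ratio[3]))  # zero cultivar diversity
})

test_that("masked-window set equals a brute-force scan of the tracks", {
  set.seed(41)
  win <- tibble::tibble(chrom = "A01", start = (0:49) * 1e5,
                        end = (1:50) * 1e5)
  pr <- runif(50, 0, 0.003); pc <- runif(50, 0, 0.003)
  race <- dplyr::mutate(win, pi = pr, n_snps = 3L, undefined = FALSE)
  cult <- dplyr::mutate(win, pi = pc, n_snps = 3L, undefined = FALSE)
  tr <- sweep_ratio_profile(race, cult)
  expect_equal(tr$masked, pr < 0.001 & pc < 0.001)
})

test_that("sweep regions merge adjacent hot windows and break on gaps", {
  tr <- make_track(c(30, 30, 5, 40))
  s <- call_sweeps(tr, 25)
  expect_equal(nrow(s), 2)
  expect_equal(s$n_windows, c(2L, 1L))

  expect_equal(nrow(call_sweeps(make_track(c(10, 25, 24)), 25)), 0)

  # a masked window breaks a region even if its ratio would qualify
  tr2 <- make_track(c(30, 30, 30), masked = c(FALSE, TRUE, FALSE))
  s2 <- call_sweeps(tr2, 25)
  expect_equal(nrow(s2), 2)
  expect_true(all(s2$n_windows == 1))

  # chromosome boundaries never merge
  tr3 <- make_track(c(30, 30), chrom = c("A01", "A02"))
  expect_equal(nrow(call_sweeps(tr3, 25)), 2)
})

test_that("sweep calling is monotone in the threshold", {
  set.seed(7)
  tr <- make_track(runif(60, 0, 60), masked = runif(60) < 0.1)
  member_windows <- function(th) {
    s <- call_sweeps(tr, th)
    unlist(purrr::map2(s$start, s$end, ~ seq(.x, .y - 1e5, by = 1e5)))
  }
  w40 <- member_windows(40)
  w20 <- member_windows(20)
  expect_true(all(w40 %in% w20))
})

test_that("planted sweeps are recovered at the scan threshold", {
  hits <- total <- 0
  for (s in 1:3) {
    cfg <- tiny_config(seed = s)
    win <- tibble::tibble(chrom = c("A01", "D01"),
                          start = c(4e4, 1e5), end = c(1e5, 1.6e5))
    g <- plant_sweeps(simulate_genotypes(cfg), win, suppression = 0.97,
                      seed = s)
    f <- maf_missing_filter(nonsingleton_filter(g))
    tiles <- tile_genome(cfg$layout, 2e4)
    race <- panel_ids(g$panel, species = "hirsutum", group = "race")
    cult <- panel_ids(g$panel, species = "hirsutum", group = "cultivar")
    tr <- sweep_ratio_profile(window_pi(f, race, tiles),
                              window_pi(f, cult, tiles))
    called <- call_sweeps(tr, 25)
    planted <- dplyr::mutate(tiles, hit = FALSE)
    for (i in seq_len(nrow(win))) {
      inw <- planted$chrom == win$chrom[i] & planted$start >= win$start[i] &
        planted$end <= win$end[i]
      for (j in which(inw)) {
        total <- total + 1
        cov <- any(called$chrom == planted$chrom[j] &
                     called$start <= planted$start[j] &
                     called$end >= planted$end[j])
        hits <- hits + cov
      }
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("permutation FPR degenerates correctly and is reproducible", {
  g <- simulate_genotypes(tiny_config(seed = 2))
  tiles <- tile_genome(tiny_layout(), 5e4)
  race <- panel_ids(g$panel, species = "hirsutum", group = "race")
  cult <- panel_ids(g$panel, species = "hirsutum", group = "cultivar")

  # threshold 0: every unmasked window exceeds it
  r0 <- permutation_fpr(g, race, cult, tiles, threshold = 0, n_perm = 5,
                        seed = 3)
  expect_true(all(r0$per_perm$exceedance == 1))

  a <- permutation_fpr(g, race, cult, tiles, n_perm = 10, seed = 11)
  b <- permutation_fpr(g, race, cult, tiles, n_perm = 10, seed = 11)
  expect_identical(a$per_perm, b$per_perm)

  expect_error(permutation_fpr(g, race[1:2], cult, tiles), "too small")
})

test_that("homoeologous sweep pairing is symmetric and skips unpaired sweeps", {
  layout <- tiny_layout()
  for (s in 1:5) {
    set.seed(s)
    # plant mirrored hot windows on a random A/D homoeologous interval,
    # plus one unpaired sweep on A02
    w0 <- sample(0:8, 1) * 2e4
    chrom <- rep(c("A01", "A02", "D01", "D02"), each = 10)
    start <- rep((0:9) * 2e4, 4)
    ratio <- rep(1, 40)
    ratio[chrom == "A01" & start == w0] <- 30
    ratio[chrom == "D01" & start == w0] <- 20
    ratio[chrom == "A02" & start == 4e4] <- 50
    tr <- tibble::tibble(chrom = chrom, start = start, end = start + 2e4,
                         pi_race = NA, pi_cultivar = NA, ratio = ratio,
                         masked = FALSE)
    sweeps <- call_sweeps(tr, 25)   # finds A01 and A02 sweeps
    pairs <- homoeolog_pairs(sweeps, tr, layout, partner_threshold = 15)
    a01 <- sweeps$sweep_id[sweeps$chrom == "A01"]
    a02 <- sweeps$sweep_id[sweeps$chrom == "A02"]
    expect_true(a01 %in% pairs$sweep_id)
    expect_false(a02 %in% pairs$sweep_id)
    # symmetric: calling from the D side finds the same pairing
    sweeps_d <- call_sweeps(tr, 15)
    pairs_d <- homoeolog_pairs(sweeps_d, tr, layout, partner_threshold = 15)
    d01 <- sweeps_d$sweep_id[sweeps_d$chrom == "D01"]
    expect_true(d01 %in% pairs_d$sweep_id)
  }
})

test_that("QTL overlap uses half-open semantics and matches brute force", {
  sweeps <- tibble::tibble(sweep_id = "s1", chrom = "A01",
                           start = 1e5, end = 2e5)
  qtl <- tibble::tibble(chrom = "A01", start = c(2e5, 1.5e5, 0),
                        end = c(3e5, 1.6e5, 5e5),
                        label = c("abut", "inside", "contains"))
  ov <- qtl_overlap(sweeps, qtl)
  expect_setequal(ov$overlaps$qtl, c("inside", "contains"))  # not "abut"

  set.seed(13)
  n <- 1000
  sw <- tibble::tibble(sweep_id = sprintf("s%03d", 1:50), chrom = "A01",
                       start = sample.int(1e6, 50))
  sw$end <- sw$start + sample.int(5e4, 50)
  q <- tibble::tibble(chrom = "A01", start = sample.int(1e6, n))
  q$end <- q$start + sample.int(3e4, n)
  q$label <- sprintf("q%04d", 1:n)
  ov <- qtl_overlap(sw, q)
  brute <- 0L
  for (i in 1:50) {
    brute <- brute + sum(q$start < sw$end[i] & q$end > sw$start[i])
  }
  expect_equal(nrow(ov$overlaps), brute)
})
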