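test_that("group reference frequency honors the half-coverage rule", {
  # 4 diploids all hom-ref -> 1.0
  gs <- geno_from_haps(matrix(0L, 3, 4), matrix(0L, 3, 4), rep("G", 4))
  expect_equal(group_ref_freq(gs, "G"), rep(1, 3))

  # genotypes 0/0, 0/1, 1/1, 0/1 -> ref freq 0.5
  a1 <- matrix(c(0L, 0L, 1L, 0L), 1)
  a2 <- matrix(c(0L, 1L, 1L, 1L), 1)
  gs2 <- geno_from_haps(a1, a2, rep("G", 4))
  expect_equal(group_ref_freq(gs2, "G"), 0.5)

  # only 1 of 4 individuals called -> undefined
  a1m <- matrix(c(0L, NA, NA, NA), 1)
  a2m <- matrix(c(1L, NA, NA, NA), 1)
  gs3 <- geno_from_haps(a1m, a2m, rep("G", 4))
  expect_true(is.na(group_ref_freq(gs3, "G")))

  # single-individual group: site must be called in that individual
  gs4 <- geno_from_haps(matrix(c(0L, NA), 2, 1),
                        matrix(c(0L, NA), 2, 1), "AP")
  expect_equal(group_ref_freq(gs4, "AP"), c(1, NA))
})

test_that("identity scores match the hand-computed window examples", {
  w <- tibble::tibble(contig = "chr1", start = 0, end = 100)
  # identical frequency profiles -> 1
  a1 <- matrix(rbinom(8, 1, 0.5), 2, 4)
  gs <- geno_from_haps(cbind(a1, a1), cbind(a1, a1),
                       rep(c("A", "B"), each = 4))
  expect_equal(identity_score_window(gs, "A", "B", w)$is_value, 1)

  # one fixed-opposite site -> 0
  gs2 <- geno_from_haps(cbind(matrix(0L, 1, 3), matrix(1L, 1, 3)),
                        cbind(matrix(0L, 1, 3), matrix(1L, 1, 3)),
                        rep(c("A", "B"), each = 3))
  expect_equal(identity_score_window(gs2, "A", "B", w)$is_value, 0)

  # |dF| = 0.2 and 0.6 -> mean IS = (0.8 + 0.4) / 2; 5 diploids/group:
  # site 1: ref freq 1.0 (A) vs 0.8 (B); site 2: 0.8 (A) vs 0.2 (B)
  a1 <- rbind(c(0, 0, 0, 0, 0,  1, 0, 0, 0, 0),
              c(1, 0, 0, 0, 0,  1, 1, 1, 1, 0))
  a2 <- rbind(c(0, 0, 0, 0, 0,  1, 0, 0, 0, 0),
              c(1, 0, 0, 0, 0,  1, 1, 1, 1, 0))
  gs3 <- geno_from_haps(a1, a2, rep(c("A", "B"), each = 5))
  out <- identity_score_window(gs3, "A", "B", w)
  expect_equal(out$is_value, (0.8 + 0.4) / 2)
  expect_equal(out$n_sites_assessed, 2L)
})

test_that("identity score is symmetric and bounded on fuzzed inputs", {
  set.seed(77)
  for (i in 1:20) {
    gs <- random_geno_set(n_sites = 30,
                          groups = c(A = sample(2:8, 1),
                                     B = sample(2:8, 1)),
                          miss_rate = runif(1, 0, 0.4))
    w <- make_windows(c(chr1 = 3000), 1000, 1000)
    ab <- identity_score_window(gs, "A", "B", w)
    ba <- identity_score_window(gs, "B", "A", w)
    expect_equal(ab$is_value, ba$is_value)
    ok <- !is.na(ab$is_value)
    expect_true(all(ab$is_value[ok] >= 0 & ab$is_value[ok] <= 1))
  }
})

test_that("ancient classification applies the margin rule", {
  reg <- tibble::tibble(contig = "c", start = c(0, 0, 0, 0),
                        end = 10)
  out <- classify_ancient(reg,
                          is_ap_chd = c(0.95, 0.65, 0.70, NA),
                          is_ap_euw = c(0.60, 0.60, 0.60, 0.5),
                          margin = 0.1)
  expect_equal(out$ancient_call,
               c("pre_introgression_selection",
                 "introgression_then_selection",
                 "ambiguous",
                 "no_data"))
})

test_that("a fully missing ancient genome yields no_data through the region path", {
  sim <- simulate_cohort(sim_config(
    n_contigs = 1, contig_length = 1e5,
    n_regions = c(uni_introgression = 2),
    samples_per_group = c(CHW = 6, CHD = 6, EUW = 6, EUD = 6, AP = 1),
    ancient_missing_rate = 1, seed = 3))
  w <- make_windows(sim$contigs)
  is_chd <- identity_score_window(sim$dataset, "AP", "CHD", w)
  is_euw <- identity_score_window(sim$dataset, "AP", "EUW", w)
  out <- classify_ancient(sim$truth,
                          region_identity_score(is_chd, sim$truth),
                          region_identity_score(is_euw, sim$truth))
  expect_true(all(out$ancient_call == "no_data"))
})

test_that("IBD proxy segments behave on constructed haplotype pairs", {
  n_sites <- 300
  hap <- rbinom(n_sites, 1, 0.5)
  mk <- function(h1a, h1b, h2a, h2b) {
    geno_set(
      variants = tibble::tibble(contig = "c1",
                                pos = as.integer(seq_len(n_sites) * 100),
                                ref = "A", alt = "G"),
      samples = tibble::tibble(sample = c("x", "y"),
                               group = c("P", "Q")),
      a1 = cbind(h1a, h2a), a2 = cbind(h1b, h2b), phased = TRUE)
  }
  len <- tibble::tibble(contig = "c1", length = n_sites * 100)

  # identical haplotypes -> one segment per haplotype pair covering all
  gs <- mk(hap, hap, hap, hap)
  segs <- detect_ibd_proxy(gs, "x", "y", bin_size = 10000,
                           contig_lengths = len)
  expect_equal(nrow(segs), 4)
  expect_true(all(segs$start == 0 & segs$end == n_sites * 100))

  # complementary haplotypes -> no segments
  gs2 <- mk(hap, hap, 1L - hap, 1L - hap)
  expect_equal(nrow(detect_ibd_proxy(gs2, "x", "y", bin_size = 10000,
                                     contig_lengths = len)), 0)

  # one divergent middle bin -> two segments per pair
  hap2 <- hap
  mid <- gs$variants$pos > 10000 & gs$variants$pos <= 20000
  hap2[mid] <- 1L - hap2[mid]
  gs3 <- mk(hap, hap, hap2, hap2)
  segs3 <- detect_ibd_proxy(gs3, "x", "y", bin_size = 10000,
                            contig_lengths = len)
  expect_equal(nrow(segs3), 8)
  expect_setequal(unique(segs3$start), c(0, 20000))
})

test_that("nIBD counts cross-group haplotype pairs per bin", {
  bins <- tibble::tibble(contig = "c1", start = c(0, 10000),
                         end = c(10000, 20000))
  samples <- tibble::tibble(sample = c("x", "y"), group = c("P", "Q"))
  segs <- tibble::tibble(
    sample1 = "x", hap1 = c(1L, 2L), sample2 = "y", hap2 = c(1L, 2L),
    contig = "c1", start = 0, end = 10000)
  out <- nibd(segs, samples, "P", "Q", bins)
  expect_equal(out$t_ibd, c(4, 4))
  expect_equal(out$nibd, c(0.5, 0))

  expect_equal(nibd(segs[0, ], samples, "P", "Q", bins)$nibd, c(0, 0))

  all_pairs <- tidyr::expand_grid(hap1 = 1:2, hap2 = 1:2) |>
    dplyr::mutate(sample1 = "x", sample2 = "y", contig = "c1",
                  start = 0, end = 20000)
  expect_equal(nibd(all_pairs, samples, "P", "Q", bins)$nibd, c(1, 1))
})

test_that("nIBD of identical haplotype sets across groups is 1 in covered bins", {
  n_sites <- 200
  haps <- matrix(rbinom(n_sites * 2, 1, 0.5), n_sites, 2)
  gs <- geno_set(
    variants = tibble::tibble(contig = "c1",
                              pos = as.integer(seq_len(n_sites) * 100),
                              ref = "A", alt = "G"),
    samples = tibble::tibble(sample = c("x", "y"),
                             group = c("P", "Q")),
    a1 = cbind(haps[, 1], haps[, 1]), a2 = cbind(haps[, 2], haps[, 2]),
    phased = TRUE)
  len <- tibble::tibble(contig = "c1", length = n_sites * 100)
  bins <- make_windows(len, 10000, 10000)
  segs <- detect_ibd_proxy(gs, "x", "y", bin_size = 10000,
                           contig_lengths = len)
  out <- nibd(segs, gs$samples, "P", "Q", bins)
  # hap1-hap1 and hap2-hap2 match everywhere; cross pairs only where
  # the two haplotypes happen to agree, so at least half the pairs
  expect_true(all(out$nibd >= 0.5))
})
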