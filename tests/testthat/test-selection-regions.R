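scan_row <- function(start, zfst, contig = "c1", end = start + 20000) {
  tibble::tibble(group_a = "CHD", group_b = "CHW", contig = contig,
                 start = start, end = end, n_snps = 50L, fst = 0.5,
                 zfst = zfst, delta_af = 0.5, low_snp = FALSE)
}

test_that("candidate windows use a strict threshold", {
  rows <- dplyr::bind_rows(scan_row(0, 1.9), scan_row(10000, 2.0),
                           scan_row(20000, 2.1))
  out <- call_candidate_windows(rows, z_threshold = 2)
  expect_equal(out$start, 20000)
  expect_equal(nrow(call_candidate_windows(rows[0, ])), 0)
  # low-SNP and undefined windows never qualify
  rows$low_snp[3] <- TRUE
  expect_equal(nrow(call_candidate_windows(rows)), 0)
})

test_that("window merging forms maximal runs and is idempotent", {
  w <- tibble::tibble(contig = "c1",
                      start = c(0, 10000), end = c(20000, 30000))
  m <- merge_windows_to_regions(w)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 30000))

  w2 <- tibble::tibble(contig = "c1", start = c(0, 50000),
                       end = c(20000, 70000))
  expect_equal(nrow(merge_windows_to_regions(w2)), 2)

  # chain of 5 staggered windows
  w3 <- tibble::tibble(contig = "c1", start = seq(0, 40000, 10000),
                       end = seq(0, 40000, 10000) + 20000)
  m3 <- merge_windows_to_regions(w3)
  expect_equal(m3$end - m3$start, 20000 + 4 * 10000)

  # book-ended windows merge; idempotence
  w4 <- tibble::tibble(contig = "c1", start = c(0, 20000),
                       end = c(20000, 40000))
  m4 <- merge_windows_to_regions(w4)
  expect_equal(nrow(m4), 1)
  expect_equal(merge_windows_to_regions(m4)[c("contig", "start", "end")],
               m4[c("contig", "start", "end")])
})

test_that("common regions are bp intersections; touching does not count", {
  a <- tibble::tibble(contig = "c1", start = 0, end = 30000)
  b <- tibble::tibble(contig = "c1", start = 20000, end = 50000)
  out <- intersect_common(a, b)
  expect_equal(c(out$start, out$end), c(20000, 30000))
  expect_equal(out$classification, "common")
  expect_equal(intersect_common(out, out)[c("start", "end")],
               out[c("start", "end")])

  b2 <- tibble::tibble(contig = "c1", start = 30000, end = 50000)
  expect_equal(nrow(intersect_common(a, b2)), 0)
  # symmetry
  expect_equal(intersect_common(b, a)[c("start", "end")],
               out[c("start", "end")])
})

test_that("empirical p follows (n+1)/(n_perm+1) exactly", {
  expect_equal(perm_p(0), 1 / 1001)
  expect_equal(perm_p(10), 11 / 1001)
  expect_equal(perm_p(1000), 1)
  expect_error(perm_p(1001))
})

test_that("a fixed-difference region never loses to a permutation", {
  # CHD/EUD fixed alt, CHW/EUW fixed ref at every site; groups large
  # enough that no permutation plausibly reproduces the exact split
  n <- 12
  n_sites <- 20
  mk <- function(val) matrix(val, n_sites, n)
  a1 <- cbind(mk(1L), mk(0L), mk(1L), mk(0L))
  gs <- geno_from_haps(a1, a1,
                       rep(c("CHD", "CHW", "EUD", "EUW"), each = n))
  reg <- list(contig = "chr1", start = 0, end = 10000)
  out <- permutation_test(gs, reg,
                          list(c("CHD", "CHW"), c("EUD", "EUW")),
                          n_perm = 200, seed = 5)
  expect_equal(out$n_exceed, 0L)
  expect_equal(out$p, 1 / 201)
  expect_equal(out$fst_obs_1, 1)
  # reproducible under the same seed
  out2 <- permutation_test(gs, reg,
                           list(c("CHD", "CHW"), c("EUD", "EUW")),
                           n_perm = 200, seed = 5)
  expect_identical(out, out2)
})

test_that("the uni/bi split applies thresholds and strict H12 inequalities", {
  reg <- tibble::tibble(contig = "c1", start = c(0, 30000, 60000),
                        end = c(20000, 50000, 80000))
  zrows <- dplyr::bind_rows(
    scan_row(0, -1.5), scan_row(30000, 2.5), scan_row(60000, 0.1))
  h12s <- tidyr::expand_grid(
    region = 1:3, role = c("chw", "chd", "euw", "eud")) |>
    dplyr::mutate(contig = "c1", start = reg$start[region],
                  end = reg$end[region],
                  group = toupper(role),
                  h12 = dplyr::case_when(
                    role == "chw" ~ 0.2, role == "chd" ~ 0.6,
                    role == "euw" ~ 0.3, role == "eud" ~ 0.5),
                  n_windows = 3L)
  out <- split_uni_bi(reg, zrows, h12s)
  expect_equal(out$classification,
               c("unidirectional", "bidirectional", "common"))

  # equal H12 fails the strict inequality
  h12s2 <- dplyr::mutate(h12s,
                         h12 = ifelse(role %in% c("euw", "eud"), 0.5,
                                      h12))
  out2 <- split_uni_bi(reg, zrows, h12s2)
  expect_true(all(out2$classification == "common"))

  # missing H12 flags the region instead of classifying it
  h12s3 <- dplyr::filter(h12s, !(region == 1 & role == "eud"))
  out3 <- split_uni_bi(reg, zrows, h12s3)
  expect_true(out3$h12_missing[1])
  expect_equal(out3$classification[1], "common")
})

test_that("classification partitions the permutation-passing regions", {
  sim <- simulate_cohort(sim_config(
    n_contigs = 1, contig_length = 8e5,
    n_regions = c(neutral = 6, uni_introgression = 3,
                  bidirectional = 3),
    samples_per_group = c(CHW = 12, CHD = 12, EUW = 12, EUD = 12,
                          AP = 1),
    seed = 13))
  run <- run_pipeline(pipeline_config(
    dataset = sim$dataset, contigs = sim$contigs, n_perm = 100,
    tajima = FALSE, seed = 13))
  reg <- tidy(run)
  expect_equal(sum(run$common$perm_pass), nrow(reg))
  expect_equal(sum(reg$classification == "unidirectional") +
                 sum(reg$classification == "bidirectional") +
                 sum(reg$classification == "common"),
               nrow(reg))
})

test_that("genes attach to regions by span distance with <= boundary", {
  reg <- tibble::tibble(contig = "c1", start = 0, end = 4000)
  genes <- tibble::tibble(
    gene_id = c("g_near", "g_exact", "g_far", "g_overlap"),
    contig = "c1",
    start = c(5000, 6000, 9000, 1000),
    end = c(6000, 7000, 10000, 2000),
    strand = "+")
  out <- annotate_genes(reg, genes, max_dist = 2000)
  expect_setequal(out$gene_id, c("g_near", "g_exact", "g_overlap"))
  expect_equal(out$distance[out$gene_id == "g_near"], 1000)
  expect_equal(out$distance[out$gene_id == "g_exact"], 2000)
  expect_equal(out$distance[out$gene_id == "g_overlap"], 0)
})

test_that("DEG zone enrichment matches the hand chi-squared and flags degenerate tables", {
  # genes laid out so the 2x2 table is [[10, 90], [10, 890]]
  regions <- tibble::tibble(contig = "c1", start = 0, end = 1000)
  n_in <- 20
  n_out <- 980
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:1000),
    contig = "c1",
    start = c(rep(31000, n_in), rep(400000, n_out)),
    end = c(rep(32000, n_in), rep(401000, n_out)),
    strand = "+")
  deg <- c(rep(TRUE, 10), rep(FALSE, 10),        # in zone
           rep(TRUE, 90), rep(FALSE, 890))       # out of zone
  out <- deg_proximity_enrichment(regions, genes, deg,
                                  dmin = 20000, dmax = 250000)
  tab <- matrix(c(10, 90, 10, 890), 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(out$chi2, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(out$count_in_zone, n_in)
  expect_false(out$degenerate)

  # all genes in zone -> degenerate margin
  genes_all <- dplyr::mutate(genes, start = 31000, end = 32000)
  out2 <- deg_proximity_enrichment(regions, genes_all, deg)
  expect_true(out2$degenerate)
  expect_true(is.na(out2$p))
})

test_that("DEG flags independent of the zone give uniform-ish p-values", {
  set.seed(88)
  regions <- tibble::tibble(contig = "c1", start = 0, end = 1000)
  pos <- sample(c(50000, 500000), 400, replace = TRUE)
  genes <- tibble::tibble(gene_id = paste0("g", 1:400), contig = "c1",
                          start = pos, end = pos + 500, strand = "+")
  ps <- replicate(40, {
    deg <- sample(c(TRUE, FALSE), 400, replace = TRUE)
    deg_proximity_enrichment(regions, genes, deg)$p
  })
  expect_false(anyNA(ps))
  expect_lt(mean(ps < 0.05), 0.25)
  expect_gt(mean(ps), 0.3)
})
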