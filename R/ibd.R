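#' Bin-based identity-by-descent proxy for a sample pair
#'
#' A deliberately simple IBD caller for the nIBD summary: the genome is
#' divided into fixed bins (default 20 kb) and each of the four
#' haplotype pairs between the two samples is called IBD in a bin iff
#' the fraction of identical alleles among sites called in both
#' haplotypes is at least `identity_threshold`. Adjacent IBD bins are
#' concatenated into segments. Bins with fewer than `min_sites` shared
#' called sites are skipped (treated as non-IBD). This proxy is NOT
#' equivalent to an HMM-based caller such as Beagle fastIBD;
#' [nibd()] also accepts externally produced segment tables.
#'
#' @param gs a [geno_set()] with phased genotypes.
#' @param sample1,sample2 sample ids.
#' @param bin_size bin width in bp (default 20000).
#' @param identity_threshold minimum identical-site fraction
#'   (default 0.99).
#' @param min_sites minimum shared called sites per bin (default 5).
#' @param contig_lengths tibble (`contig`, `length`); defaults to the
#'   last variant position per contig.
#' @return tibble of segments: `sample1`, `hap1`, `sample2`, `hap2`,
#'   `contig`, `start`, `end` (0-based half-open).
#' @export
detect_ibd_proxy <- function(gs, sample1, sample2, bin_size = 20000,
                             identity_threshold = 0.99, min_sites = 5,
                             contig_lengths = NULL) {
  i1 <- match(sample1, gs$samples$sample)
  i2 <- match(sample2, gs$samples$sample)
  if (is.na(i1) || is.na(i2)) {
    stop("unknown sample id", call. = FALSE)
  }
  if (is.null(contig_lengths)) {
    contig_lengths <- gs$variants |>
      dplyr::group_by(contig = .data$contig) |>
      dplyr::summarise(length = max(.data$pos), .groups = "drop")
  }
  bins <- make_windows(contig_lengths, size = bin_size, step = bin_size)
  idx <- window_site_index(gs, bins)
  haps <- list(`1` = "a1", `2` = "a2")
  out <- purrr::map_dfr(1:2, function(h1) {
    purrr::map_dfr(1:2, function(h2) {
      x <- gs[[haps[[h1]]]][, i1]
      y <- gs[[haps[[h2]]]][, i2]
      ibd <- purrr::map_lgl(idx, function(i) {
        ok <- !is.na(x[i]) & !is.na(y[i])
        if (sum(ok) < min_sites) return(FALSE)
        mean(x[i][ok] == y[i][ok]) >= identity_threshold
      })
      segs <- bins_to_segments(bins, ibd)
      if (nrow(segs) == 0) return(NULL)
      dplyr::mutate(segs, sample1 = sample1, hap1 = h1,
                    sample2 = sample2, hap2 = h2, .before = 1)
    })
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(sample1 = character(), hap1 = integer(),
                          sample2 = character(), hap2 = integer(),
                          contig = character(), start = integer(),
                          end = integer())
  }
  out
}

# concatenate runs of TRUE bins into segments (bins are adjacent and
# sorted within each contig by construction)
bins_to_segments <- function(bins, flag) {
  purrr::map_dfr(split(seq_len(nrow(bins)), bins$contig), function(rows) {
    f <- flag[rows]
    if (!any(f)) return(NULL)
    r <- rle(f)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1
    keep <- which(r$values)
    tibble::tibble(contig = bins$contig[rows[1]],
                   start = bins$start[rows[starts_i[keep]]],
                   end = bins$end[rows[ends_i[keep]]])
  })
}

#' Normalized IBD sharing between two groups, per bin
#'
#' `nIBD = cIBD / tIBD` where, per bin, `cIBD` counts cross-group
#' haplotype pairs whose IBD segments cover the bin and
#' `tIBD = (2 n1) * (2 n2)` is the total number of cross-group
#' haplotype comparisons.
#'
#' @param segments segment tibble as produced by [detect_ibd_proxy()]
#'   (or read from an external caller): `sample1`, `hap1`, `sample2`,
#'   `hap2`, `contig`, `start`, `end`.
#' @param samples tibble (`sample`, `group`) mapping samples to groups.
#' @param group1,group2 the two groups.
#' @param bins tibble of bins (`contig`, `start`, `end`), e.g.
#'   `make_windows(contigs, 20000, 20000)`.
#' @return `bins` with added columns `c_ibd`, `t_ibd`, `nibd`.
#' @export
nibd <- function(segments, samples, group1, group2, bins) {
  n1 <- sum(samples$group == group1)
  n2 <- sum(samples$group == group2)
  if (n1 == 0 || n2 == 0) stop("empty group", call. = FALSE)
  t_ibd <- (2 * n1) * (2 * n2)
  g <- function(s) samples$group[match(s, samples$sample)]
  cross <- (g(segments$sample1) == group1 & g(segments$sample2) == group2) |
    (g(segments$sample1) == group2 & g(segments$sample2) == group1)
  segs <- segments[cross & !is.na(cross), , drop = FALSE]
  c_ibd <- purrr::pmap_int(bins[c("contig", "start", "end")],
                           function(contig, start, end) {
    covers <- segs$contig == contig & segs$start <= start & segs$end >= end
    # one haplotype pair can contribute at most once per bin
    sum(!duplicated(segs[covers, c("sample1", "hap1", "sample2", "hap2")]))
  })
  dplyr::mutate(bins, c_ibd = c_ibd, t_ibd = t_ibd,
                nibd = c_ibd / t_ibd)
}
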