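#' H12 from a haplotype frequency spectrum
#'
#' Haplotype homozygosity after pooling the two most frequent
#' haplotype classes: `(p1 + p2)^2 + sum_{i>2} p_i^2`. With a single
#' distinct haplotype `p2 = 0` and H12 = 1. Sensitive to both hard and
#' soft sweeps.
#'
#' @param freqs numeric vector of haplotype class frequencies summing
#'   to 1 (sorted internally).
#' @return H12 value in (0, 1].
#' @examples
#' h12(c(0.25, 0.25, 0.25, 0.25))  # 0.375
#' @export
h12 <- function(freqs) {
  if (length(freqs) == 0) stop("empty haplotype spectrum", call. = FALSE)
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("haplotype frequencies must sum to 1", call. = FALSE)
  }
  p <- sort(freqs, decreasing = TRUE)
  p12 <- p[1] + if (length(p) >= 2) p[2] else 0
  p12^2 + if (length(p) > 2) sum(p[-(1:2)]^2) else 0
}

# distinct-haplotype class frequencies for a 2n x w allele matrix;
# haplotypes with any missing call are dropped. Windows of <= 52
# binary sites are keyed exactly as base-2 integers (< 2^53, so exact
# in doubles); wider windows fall back to string keys.
hap_spectrum <- function(hmat) {
  keep <- !apply(is.na(hmat), 1, any)
  hmat <- hmat[keep, , drop = FALSE]
  if (nrow(hmat) == 0) return(NULL)
  key <- if (ncol(hmat) <= 52) {
    as.vector(hmat %*% 2^(seq_len(ncol(hmat)) - 1))
  } else {
    apply(hmat, 1, paste, collapse = "")
  }
  counts <- table(key)
  list(freqs = sort(as.vector(counts) / sum(counts), decreasing = TRUE),
       n_haps = nrow(hmat))
}

# haplotype allele matrix (2n rows) for a group, one contig's sites
hap_matrix <- function(gs, cols, sites) {
  rbind(t(gs$a1[sites, cols, drop = FALSE]),
        t(gs$a2[sites, cols, drop = FALSE]))
}

#' H12 scan in SNP-count windows
#'
#' Per contig, windows of `window_snps` consecutive SNPs advancing
#' `step_snps` SNPs (defaults 50 and 10, the usual soft-sweep scan
#' grid). Haplotype classes are defined by exact allele-string
#' equality; haplotypes with any missing call in a window are dropped
#' before the spectrum is built. Requires phased genotypes. Contigs
#' with fewer SNPs than one window produce no rows (with a message).
#'
#' @param gs a [geno_set()] with phased genotypes.
#' @param group group label.
#' @param window_snps window size in SNPs (default 50).
#' @param step_snps distance between window centers in SNPs
#'   (default 10).
#' @return tibble: `contig`, `center_snp_index` (1-based within
#'   contig), `center_pos`, `first_pos`, `last_pos`, `group`, `h12`,
#'   `n_haps`.
#' @export
h12_scan <- function(gs, group, window_snps = 50, step_snps = 10) {
  stopifnot(window_snps >= 1, step_snps >= 1)
  cols <- group_cols(gs, group)
  check_phased(gs, cols)
  contigs <- unique(gs$variants$contig)
  purrr::map_dfr(contigs, function(ctg) {
    sites <- which(gs$variants$contig == ctg)
    n <- length(sites)
    if (n < window_snps) {
      message("h12_scan: contig ", ctg, " has ", n,
              " SNPs (< ", window_snps, "), skipped")
      return(NULL)
    }
    H <- hap_matrix(gs, cols, sites)
    starts <- seq(1, n - window_snps + 1, by = step_snps)
    purrr::map_dfr(starts, function(s) {
      w <- s:(s + window_snps - 1)
      sp <- hap_spectrum(H[, w, drop = FALSE])
      center <- s + ceiling(window_snps / 2) - 1L
      tibble::tibble(
        contig = ctg,
        center_snp_index = as.integer(center),
        center_pos = gs$variants$pos[sites[center]],
        first_pos = gs$variants$pos[sites[s]],
        last_pos = gs$variants$pos[sites[s + window_snps - 1]],
        group = group,
        h12 = if (is.null(sp)) NA_real_ else h12(sp$freqs),
        n_haps = if (is.null(sp)) 0L else sp$n_haps
      )
    })
  })
}

check_phased <- function(gs, cols) {
  ph <- gs$phased[, cols, drop = FALSE]
  called <- !is.na(gs$a1[, cols, drop = FALSE]) &
    !is.na(gs$a2[, cols, drop = FALSE])
  if (any(!ph & called)) {
    stop("h12 requires phased genotypes; unphased calls found ",
         "(phase upstream, e.g. with Beagle)", call. = FALSE)
  }
}

#' Sample-size-matched H12 for a larger (domestic) group
#'
#' H12 rises mechanically with smaller sample size, so comparing a
#' large domestic group against a smaller wild group is biased. This
#' draws `reps` random subsamples of `wild_group_size` individuals
#' (both haplotypes of an individual taken together) from the domestic
#' group, runs [h12_scan()] on each, and reports the per-window
#' arithmetic mean across replicates.
#'
#' @inheritParams h12_scan
#' @param domestic_group group to subsample.
#' @param wild_group_size target number of individuals.
#' @param reps number of subsample replicates (default 10).
#' @param seed integer seed controlling the draws.
#' @return tibble as [h12_scan()], with `h12` the replicate mean and
#'   an added `reps` column.
#' @export
h12_subsampled <- function(gs, domestic_group, wild_group_size, reps = 10,
                           seed = 1, window_snps = 50, step_snps = 10) {
  cols <- group_cols(gs, domestic_group)
  if (length(cols) < wild_group_size) {
    stop("group '", domestic_group, "' (", length(cols), ") is smaller ",
         "than wild_group_size (", wild_group_size, "); swap the roles ",
         "of the groups", call. = FALSE)
  }
  runs <- withr::with_seed(seed, {
    purrr::map(seq_len(reps), function(r) {
      keep <- sort(sample(cols, wild_group_size))
      sub <- gs
      sub$samples <- gs$samples[keep, , drop = FALSE]
      sub$a1 <- gs$a1[, keep, drop = FALSE]
      sub$a2 <- gs$a2[, keep, drop = FALSE]
      sub$phased <- gs$phased[, keep, drop = FALSE]
      suppressMessages(
        h12_scan(sub, domestic_group, window_snps, step_snps))
    })
  })
  out <- runs[[1]]
  if (nrow(out) == 0) return(dplyr::mutate(out, reps = integer(0)))
  hmat <- do.call(cbind, purrr::map(runs, "h12"))
  out$h12 <- rowMeans(hmat, na.rm = TRUE)
  out$h12[is.nan(out$h12)] <- NA_real_
  out$n_haps <- as.integer(round(rowMeans(
    do.call(cbind, purrr::map(runs, "n_haps")))))
  dplyr::mutate(out, reps = as.integer(reps))
}

#' Region-level H12 summary
#'
#' Maps SNP-indexed H12 rows onto bp-coordinate regions: the region
#' summary is the maximum `h12` over scan rows whose window center
#' falls inside the region extent (max preserves sweep peaks). Regions
#' with no centered row get `NA`.
#'
#' @param rows tibble from [h12_scan()] or [h12_subsampled()]
#'   (possibly several groups bound together).
#' @param regions tibble with `contig`, `start`, `end` (0-based
#'   half-open).
#' @return tibble: region columns plus `group`, `h12`, `n_windows`.
#' @export
region_h12 <- function(rows, regions) {
  purrr::pmap_dfr(regions[c("contig", "start", "end")],
                  function(contig, start, end) {
    inside <- rows$contig == contig &
      (rows$center_pos - 1) >= start & (rows$center_pos - 1) < end
    sub <- rows[inside, , drop = FALSE]
    sub |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        h12 = if (all(is.na(.data$h12))) NA_real_
              else max(.data$h12, na.rm = TRUE),
        n_windows = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(contig = contig, start = start, end = end,
                    .before = 1)
  })
}
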