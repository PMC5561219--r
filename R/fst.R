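#' Per-site Weir & Cockerham (1984) variance components
#'
#' Computes, for every requested site, the three variance components of
#' the two-population Weir-Cockerham Fst estimator: `a` (among
#' populations), `b` (among individuals within populations) and `c`
#' (within individuals), using observed heterozygosity. Missing
#' genotypes are excluded from the per-population sample sizes; an
#' individual counts as called only when both alleles are called.
#'
#' Sites where either population has no called individual, or where the
#' average sample size is 1, have undefined components (`NA`).
#'
#' @param gs a [geno_set()].
#' @param group_a,group_b group labels of the two populations.
#' @param sites integer vector of variant row indices (default: all).
#' @return tibble with one row per site: `site`, `a`, `b`, `c`.
#' @export
site_fst_components <- function(gs, group_a, group_b, sites = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(gs$variants))
  sa <- site_summary(gs, group_cols(gs, group_a), sites)
  sb <- site_summary(gs, group_cols(gs, group_b), sites)
  comp <- wc_components(sa$n, sa$p, sa$h, sb$n, sb$p, sb$h)
  tibble::tibble(site = sites, a = comp$a, b = comp$b, c = comp$c)
}

# per-site called sample size n, ALT frequency p and observed
# heterozygote frequency h for one set of sample columns
site_summary <- function(gs, cols, sites) {
  a1 <- gs$a1[sites, cols, drop = FALSE]
  a2 <- gs$a2[sites, cols, drop = FALSE]
  called <- !is.na(a1) & !is.na(a2)
  n <- rowSums(called)
  ac <- a1 + a2
  ac[!called] <- NA_integer_
  alt <- rowSums(ac, na.rm = TRUE)
  het <- rowSums(ac == 1L, na.rm = TRUE)
  list(n = n, p = ifelse(n > 0, alt / (2 * n), NA_real_),
       h = ifelse(n > 0, het / n, NA_real_))
}

# Weir & Cockerham (1984) components for r = 2 populations, vectorized
# over sites; ALT taken as the scored allele (the estimator is
# allele-symmetric)
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  defined <- n1 > 0 & n2 > 0 & nbar > 1
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!defined] <- NA_real_
  b[!defined] <- NA_real_
  cc[!defined] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham Fst (ratio of sums)
#'
#' Window Fst is the sum of the per-site `a` components divided by the
#' sum of `a + b + c` over sites with defined components — the
#' "weighted" windowed convention of vcftools. Windows where the
#' denominator is zero (e.g. all sites monomorphic) have undefined Fst.
#' Negative window values are retained, not clamped: clamping would
#' distort the genome-wide Z null.
#'
#' @inheritParams site_fst_components
#' @param contrast character vector of two group labels, e.g.
#'   `c("CHD", "CHW")`.
#' @param windows window tibble from [make_windows()].
#' @param min_snps windows with fewer variants are flagged `low_snp`
#'   and excluded from Z-transformation (default 10).
#' @return tibble: `contig`, `start`, `end`, `n_snps`, `fst`,
#'   `low_snp`.
#' @export
windowed_fst <- function(gs, contrast, windows, min_snps = 10) {
  stopifnot(length(contrast) == 2)
  if (nrow(windows) == 0) stop("empty window set", call. = FALSE)
  comp <- site_fst_components(gs, contrast[1], contrast[2])
  tot <- comp$a + comp$b + comp$c
  idx <- window_site_index(gs, windows)
  res <- purrr::map(idx, function(i) {
    ai <- comp$a[i]
    ti <- tot[i]
    ok <- !is.na(ti)
    denom <- sum(ti[ok])
    # all assessed sites monomorphic in the pooled pair: the window
    # shows zero differentiation, reported as 0 rather than undefined
    fst <- if (sum(ok) == 0) NA_real_
           else if (denom == 0) 0
           else sum(ai[ok]) / denom
    c(n = length(i), fst = fst)
  })
  m <- do.call(rbind, res)
  windows |>
    dplyr::mutate(n_snps = as.integer(unname(m[, "n"])),
                  fst = unname(m[, "fst"]),
                  low_snp = .data$n_snps < min_snps)
}

#' Z-score transformation
#'
#' Centers and scales by the sample standard deviation (`n - 1`
#' denominator). `NA` inputs propagate as `NA` and are excluded from
#' the mean/sd. A constant vector is a degenerate scan and errors.
#'
#' @param values numeric vector.
#' @return numeric vector of z-values.
#' @export
zscore <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) {
    stop("zscore needs at least 2 defined values", call. = FALSE)
  }
  s <- stats::sd(values[ok])
  if (s == 0) {
    stop("zscore: zero standard deviation (degenerate scan)", call. = FALSE)
  }
  (values - mean(values[ok])) / s
}

#' Windowed absolute allele-frequency difference
#'
#' Per-site `|freq_A - freq_B|` of the ALT allele (among called
#' alleles), averaged over sites where both groups have at least one
#' called allele.
#'
#' @inheritParams windowed_fst
#' @return tibble: `contig`, `start`, `end`, `delta_af`.
#' @export
delta_af <- function(gs, contrast, windows) {
  stopifnot(length(contrast) == 2)
  fa <- allele_freq(gs, group_cols(gs, contrast[1]))
  fb <- allele_freq(gs, group_cols(gs, contrast[2]))
  d <- abs(fa - fb)
  idx <- window_site_index(gs, windows)
  windows |>
    dplyr::mutate(delta_af = purrr::map_dbl(idx, function(i) {
      di <- d[i]
      if (all(is.na(di)) || length(di) == 0) NA_real_ else mean(di, na.rm = TRUE)
    }))
}

# ALT-allele frequency among all called alleles (half-called
# individuals contribute their called allele)
allele_freq <- function(gs, cols, sites = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(gs$variants))
  a1 <- gs$a1[sites, cols, drop = FALSE]
  a2 <- gs$a2[sites, cols, drop = FALSE]
  called <- rowSums(!is.na(a1)) + rowSums(!is.na(a2))
  alt <- rowSums(a1, na.rm = TRUE) + rowSums(a2, na.rm = TRUE)
  ifelse(called > 0, alt / called, NA_real_)
}

#' Sliding-window selection scan for one or more contrasts
#'
#' Convenience wrapper running [windowed_fst()], genome-wide
#' [zscore()] of the retained windows, [delta_af()] and (optionally)
#' [tajimas_d()] for both groups of each contrast, returning one tidy
#' tibble.
#'
#' @inheritParams windowed_fst
#' @param contrasts list of 2-element character vectors.
#' @param tajima compute per-group Tajima's D (default TRUE).
#' @return tibble with one row per window per contrast: `group_a`,
#'   `group_b`, `contig`, `start`, `end`, `n_snps`, `fst`, `zfst`,
#'   `delta_af`, `tajima_d_a`, `tajima_d_b`, `low_snp`.
#' @export
window_scan <- function(gs, contrasts, windows, min_snps = 10,
                        tajima = TRUE) {
  if (!is.list(contrasts)) contrasts <- list(contrasts)
  taj_cache <- new.env(parent = emptyenv())
  taj_for <- function(group) {
    if (!tajima) return(rep(NA_real_, nrow(windows)))
    if (is.null(taj_cache[[group]])) {
      taj_cache[[group]] <- tajimas_d(gs, group, windows)$tajima_d
    }
    taj_cache[[group]]
  }
  purrr::map_dfr(contrasts, function(ct) {
    wf <- windowed_fst(gs, ct, windows, min_snps = min_snps)
    z <- rep(NA_real_, nrow(wf))
    use <- !wf$low_snp & !is.na(wf$fst)
    z[use] <- zscore(wf$fst[use])
    daf <- delta_af(gs, ct, windows)$delta_af
    tibble::tibble(
      group_a = ct[1], group_b = ct[2],
      contig = wf$contig, start = wf$start, end = wf$end,
      n_snps = wf$n_snps, fst = wf$fst, zfst = z, delta_af = daf,
      tajima_d_a = taj_for(ct[1]), tajima_d_b = taj_for(ct[2]),
      low_snp = wf$low_snp
    )
  })
}
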