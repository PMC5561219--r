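#' Windowed Tajima's D for one group
#'
#' Standard Tajima (1989) D contrasting mean pairwise differences (pi)
#' with the scaled number of segregating sites (S / a1). With missing
#' data, each site is restricted to its called alleles: the per-site
#' contribution to pi is `2 k (m - k) / (m (m - 1))` for `k` ALT
#' alleles among `m` called, S counts sites polymorphic among called
#' alleles, and the sample size entering the constants is the floor of
#' the mean per-site called-allele count over the window. Windows with
#' `S = 0` or fewer than 4 usable chromosomes are undefined (`NA`),
#' flagged rather than raised.
#'
#' @inheritParams windowed_fst
#' @param group group label.
#' @return tibble: `contig`, `start`, `end`, `n_snps`, `S`,
#'   `tajima_d`.
#' @export
tajimas_d <- function(gs, group, windows) {
  cols <- group_cols(gs, group)
  a1 <- gs$a1[, cols, drop = FALSE]
  a2 <- gs$a2[, cols, drop = FALSE]
  m <- rowSums(!is.na(a1)) + rowSums(!is.na(a2))
  k <- rowSums(a1, na.rm = TRUE) + rowSums(a2, na.rm = TRUE)
  seg <- k > 0 & k < m
  pi_site <- ifelse(m > 1, 2 * k * (m - k) / (m * (m - 1)), NA_real_)
  idx <- window_site_index(gs, windows)
  res <- purrr::map(idx, function(i) {
    if (length(i) == 0) return(c(n = 0, S = NA_real_, D = NA_real_))
    mi <- m[i]
    use <- mi > 1
    if (!any(use)) return(c(n = length(i), S = NA_real_, D = NA_real_))
    S <- sum(seg[i][use])
    n <- floor(mean(mi[use]))
    if (S == 0 || n < 4) {
      return(c(n = length(i), S = S, D = NA_real_))
    }
    pi <- sum(pi_site[i][use])
    c(n = length(i), S = S, D = tajima_d_from_summaries(pi, S, n))
  })
  mm <- do.call(rbind, res)
  windows |>
    dplyr::mutate(n_snps = as.integer(unname(mm[, "n"])),
                  S = unname(mm[, "S"]),
                  tajima_d = unname(mm[, "D"]))
}

# Tajima (1989) closed form from pi, S and chromosome count n
tajima_d_from_summaries <- function(pi, S, n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}
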