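#' Empirical p-value from permutation counts
#'
#' `p = (n_exceed + 1) / (n_perm + 1)`, so 1000 permutations give a
#' minimum attainable p of 1/1001 and a maximum of exactly 1.
#'
#' @param n_exceed number of permuted statistics at least as extreme
#'   as the observed one.
#' @param n_perm number of permutations (default 1000).
#' @return empirical p-value in `[1/(n_perm+1), 1]`.
#' @export
perm_p <- function(n_exceed, n_perm = 1000) {
  stopifnot(all(n_exceed >= 0), all(n_exceed <= n_perm))
  (n_exceed + 1) / (n_perm + 1)
}

#' Permutation test of a region's domestic-vs-wild differentiation
#'
#' Recomputes the region's Weir-Cockerham Fst (ratio of sums over the
#' region's sites) under label permutations in which group sizes are
#' held constant. Labels are shuffled within each contrast's sample
#' pool independently (e.g. among CHD+CHW, and among EUD+EUW). The
#' default `rule = "max"` computes a per-contrast empirical p-value
#' and reports the maximum — a valid level-alpha test of the
#' intersection hypothesis "differentiated in both contrasts".
#' `rule = "joint"` instead counts a permutation iff its permuted Fst
#' is at least the observed Fst in BOTH contrasts simultaneously;
#' note that under an exchangeable null this joint p behaves like the
#' product of two uniforms and is anticonservative when compared with
#' a nominal per-region level.
#'
#' @inheritParams site_fst_components
#' @param region one-row tibble or list with `contig`, `start`, `end`
#'   (0-based half-open).
#' @param contrasts list of 2-element group-label vectors (domestic,
#'   wild); default the two domestication contrasts is supplied by the
#'   pipeline.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param rule `"max"` (default) or `"joint"`; see Details.
#' @return one-row tibble: `n_exceed`, `n_perm`, `p`, plus observed
#'   per-contrast Fst columns `fst_obs_1`, `fst_obs_2`, ...
#' @export
permutation_test <- function(gs, region, contrasts, n_perm = 1000,
                             seed = 1, rule = c("max", "joint")) {
  rule <- match.arg(rule)
  sites <- which(gs$variants$contig == region$contig &
                   (gs$variants$pos - 1) >= region$start &
                   (gs$variants$pos - 1) < region$end)
  if (length(sites) == 0) {
    stop("region has no SNPs", call. = FALSE)
  }
  pools <- purrr::map(contrasts, function(ct) {
    ca <- group_cols(gs, ct[1])
    cb <- group_cols(gs, ct[2])
    a1 <- gs$a1[sites, c(ca, cb), drop = FALSE]
    a2 <- gs$a2[sites, c(ca, cb), drop = FALSE]
    called <- !is.na(a1) & !is.na(a2)
    ac <- a1 + a2
    ac[!called] <- 0L          # zero contribution from uncalled
    het <- (ac == 1L) & called
    list(n_a = length(ca), n_tot = length(ca) + length(cb),
         called = called, ac = ac, het = het)
  })
  region_fst <- function(pool, cols_a) {
    cols_b <- setdiff(seq_len(pool$n_tot), cols_a)
    f <- function(cols) {
      n <- rowSums(pool$called[, cols, drop = FALSE])
      alt <- rowSums(pool$ac[, cols, drop = FALSE])
      het <- rowSums(pool$het[, cols, drop = FALSE])
      list(n = n, p = ifelse(n > 0, alt / (2 * n), NA_real_),
           h = ifelse(n > 0, het / n, NA_real_))
    }
    sa <- f(cols_a)
    sb <- f(cols_b)
    comp <- wc_components(sa$n, sa$p, sa$h, sb$n, sb$p, sb$h)
    tot <- comp$a + comp$b + comp$c
    ok <- !is.na(tot)
    denom <- sum(tot[ok])
    if (denom == 0) NA_real_ else sum(comp$a[ok]) / denom
  }
  obs <- purrr::map_dbl(pools, function(p) region_fst(p, seq_len(p$n_a)))
  perm <- withr::with_seed(seed, {
    purrr::map(seq_len(n_perm), function(i) {
      purrr::map_dbl(pools, function(p) {
        region_fst(p, sample.int(p$n_tot, p$n_a))
      })
    })
  })
  pm <- do.call(rbind, perm)
  ge <- sweep(pm, 2, obs, `>=`)
  ge[is.na(ge)] <- FALSE
  if (rule == "joint") {
    n_exceed <- sum(rowSums(ge) == length(pools))
    p <- perm_p(n_exceed, n_perm)
  } else {
    per <- colSums(ge)
    n_exceed <- max(per)
    p <- max(perm_p(per, n_perm))
  }
  out <- tibble::tibble(n_exceed = n_exceed, n_perm = n_perm, p = p)
  for (i in seq_along(obs)) out[[paste0("fst_obs_", i)]] <- obs[i]
  out
}
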