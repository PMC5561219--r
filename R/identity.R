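#' Reference-allele frequency per group under the half-coverage rule
#'
#' The frequency of the REF allele among called alleles, defined only
#' at sites where at least half of the group's individuals are fully
#' called (both alleles). For a single-individual group (e.g. the
#' ancient sample) this means the site must be called in that
#' individual.
#'
#' @inheritParams site_fst_components
#' @param group group label.
#' @param sites integer variant row indices (default: all).
#' @return numeric vector of REF frequencies (`NA` where undefined).
#' @export
group_ref_freq <- function(gs, group, sites = NULL) {
  cols <- group_cols(gs, group)
  if (is.null(sites)) sites <- seq_len(nrow(gs$variants))
  a1 <- gs$a1[sites, cols, drop = FALSE]
  a2 <- gs$a2[sites, cols, drop = FALSE]
  full <- rowSums(!is.na(a1) & !is.na(a2))
  called <- rowSums(!is.na(a1)) + rowSums(!is.na(a2))
  alt <- rowSums(a1, na.rm = TRUE) + rowSums(a2, na.rm = TRUE)
  f <- 1 - alt / called
  f[2 * full < length(cols) | called == 0] <- NA_real_
  f
}

#' Windowed identity score between two groups
#'
#' Per assessed site `IS = 1 - |F_g1 - F_g2|`, where `F` is the
#' REF-allele frequency of [group_ref_freq()]; a site is assessed only
#' when both groups pass the half-coverage rule. The window value is
#' the mean over assessed sites; windows with none are undefined.
#'
#' @inheritParams windowed_fst
#' @param g1,g2 group labels (IS is symmetric in the pair).
#' @return tibble: `contig`, `start`, `end`, `group1`, `group2`,
#'   `is_value`, `n_sites_assessed`.
#' @export
identity_score_window <- function(gs, g1, g2, windows) {
  f1 <- group_ref_freq(gs, g1)
  f2 <- group_ref_freq(gs, g2)
  is_site <- 1 - abs(f1 - f2)
  idx <- window_site_index(gs, windows)
  res <- purrr::map(idx, function(i) {
    v <- is_site[i]
    ok <- !is.na(v)
    c(n = sum(ok), is = if (any(ok)) mean(v[ok]) else NA_real_)
  })
  m <- do.call(rbind, res)
  windows |>
    dplyr::mutate(group1 = g1, group2 = g2,
                  is_value = unname(m[, "is"]),
                  n_sites_assessed = as.integer(unname(m[, "n"])))
}

#' Region-level identity score
#'
#' Unweighted mean of the member-window IS values over windows
#' overlapping each region extent; `NA` if no member window has a
#' defined value.
#'
#' @param is_rows tibble from [identity_score_window()].
#' @param regions tibble with `contig`, `start`, `end`.
#' @return numeric vector, one value per region row.
#' @export
region_identity_score <- function(is_rows, regions) {
  purrr::pmap_dbl(regions[c("contig", "start", "end")],
                  function(contig, start, end) {
    sel <- is_rows$contig == contig &
      is_rows$start < end & is_rows$end > start
    v <- is_rows$is_value[sel]
    if (all(is.na(v)) || length(v) == 0) NA_real_ else mean(v, na.rm = TRUE)
  })
}

#' Classify unidirectional regions with the ancient-genome identity test
#'
#' For each region, compares the identity score of the ancient sample
#' against the Chinese domestic group (`is_ap_chd`) with its score
#' against the European wild group (`is_ap_euw`), using a margin
#' (default 0.1) to absorb baseline differences:
#' * `is_ap_chd < is_ap_euw + margin` — the ancient genome resembles
#'   European wild boar: the selected haplotype arrived later by
#'   introgression (`introgression_then_selection`);
#' * `is_ap_chd > is_ap_euw + margin` — the ancient genome already
#'   resembles Chinese domestic pigs: selection predates the sampled
#'   era (`pre_introgression_selection`);
#' * equality exactly at the margin — `ambiguous`;
#' * either score undefined (e.g. the ancient genome has no coverage
#'   in the region) — `no_data`.
#'
#' @param regions tibble with `contig`, `start`, `end`.
#' @param is_ap_chd,is_ap_euw numeric vectors of region-level identity
#'   scores (see [region_identity_score()]).
#' @param margin decision margin on the IS scale (default 0.1).
#' @return `regions` with added columns `is_ap_chd`, `is_ap_euw`,
#'   `ancient_call`.
#' @export
classify_ancient <- function(regions, is_ap_chd, is_ap_euw, margin = 0.1) {
  stopifnot(length(is_ap_chd) == nrow(regions),
            length(is_ap_euw) == nrow(regions))
  call <- dplyr::case_when(
    is.na(is_ap_chd) | is.na(is_ap_euw) ~ "no_data",
    is_ap_chd < is_ap_euw + margin ~ "introgression_then_selection",
    is_ap_chd > is_ap_euw + margin ~ "pre_introgression_selection",
    TRUE ~ "ambiguous"
  )
  dplyr::mutate(regions, is_ap_chd = is_ap_chd, is_ap_euw = is_ap_euw,
                ancient_call = call)
}
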