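#' Candidate selected windows from a Z-transformed scan
#'
#' Windows with `zfst` strictly greater than the threshold (default 2)
#' for one contrast. Low-SNP and undefined windows never qualify.
#'
#' @param rows scan tibble from [window_scan()] (one contrast, or
#'   filter by `group_a`/`group_b` first).
#' @param z_threshold ZFst cutoff (strict `>`, default 2).
#' @return tibble of candidate windows (`contig`, `start`, `end`,
#'   `zfst`, ...).
#' @export
call_candidate_windows <- function(rows, z_threshold = 2) {
  dplyr::filter(rows, !is.na(.data$zfst), !.data$low_snp,
                .data$zfst > z_threshold)
}

#' Merge overlapping or book-ended windows into regions
#'
#' Maximal runs of windows that overlap or touch (`start <= current
#' end`) are merged per contig; the operation is idempotent.
#'
#' @param windows tibble with `contig`, `start`, `end` (any extra
#'   columns are dropped).
#' @return tibble of regions: `contig`, `start`, `end`, `n_windows`.
#' @export
merge_windows_to_regions <- function(windows) {
  if (nrow(windows) == 0) {
    return(tibble::tibble(contig = character(), start = numeric(),
                          end = numeric(), n_windows = integer()))
  }
  windows |>
    dplyr::select("contig", "start", "end") |>
    dplyr::arrange(.data$contig, .data$start, .data$end) |>
    dplyr::group_by(.data$contig) |>
    dplyr::mutate(
      new_run = .data$start > dplyr::lag(cummax(.data$end),
                                         default = -Inf),
      run = cumsum(.data$new_run)) |>
    dplyr::group_by(.data$contig, .data$run) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     n_windows = dplyr::n(), .groups = "drop") |>
    dplyr::select("contig", "start", "end", "n_windows") |>
    dplyr::arrange(.data$contig, .data$start)
}

#' Regions shared by the two domestic scans
#'
#' Intersects two region sets: every pair of regions overlapping by at
#' least 1 bp yields a common region whose extent is the intersection.
#' Book-ended (touching) regions do not count as shared.
#'
#' @param regions_a,regions_b region tibbles (`contig`, `start`,
#'   `end`).
#' @return tibble of common regions with `classification = "common"`.
#' @export
intersect_common <- function(regions_a, regions_b) {
  out <- dplyr::inner_join(
    dplyr::select(regions_a, "contig", a_start = "start", a_end = "end"),
    dplyr::select(regions_b, "contig", b_start = "start", b_end = "end"),
    by = "contig", relationship = "many-to-many") |>
    dplyr::filter(pmax(.data$a_start, .data$b_start) <
                    pmin(.data$a_end, .data$b_end)) |>
    dplyr::transmute(contig = .data$contig,
                     start = pmax(.data$a_start, .data$b_start),
                     end = pmin(.data$a_end, .data$b_end),
                     classification = "common") |>
    dplyr::arrange(.data$contig, .data$start)
  out
}

#' Split permutation-passing common regions into unidirectional and
#' bidirectional classes
#'
#' A common region becomes
#' * `unidirectional` iff its CHD-vs-EUD region ZFst is strictly below
#'   `uni_threshold` (default -1) and H12 is elevated in both domestic
#'   groups over their wild counterparts (`H12_CHD > H12_CHW` and
#'   `H12_EUD > H12_EUW`, strict);
#' * `bidirectional` iff the region ZFst is strictly above
#'   `bi_threshold` (default 2) with the same two H12 inequalities;
#' * otherwise it stays `common`.
#'
#' The region-level ZFst is the length-weighted mean of member-window
#' ZFst over the common extent (weights are overlap lengths);
#' `zfst_summary = "max"` uses the maximum instead. Regions with any
#' missing H12 summary are flagged (`h12_missing`) and left
#' unclassified.
#'
#' @param common_regions tibble of common regions (`contig`, `start`,
#'   `end`).
#' @param zfst_chd_eud_rows [window_scan()] rows for the
#'   domestic-vs-domestic contrast.
#' @param h12_summary tibble from [region_h12()] covering the four
#'   core groups on these regions, with a `role` column mapping each
#'   group to `chw`/`chd`/`euw`/`eud` (see [run_pipeline()]), or the
#'   group labels themselves if they already are those roles
#'   (case-insensitive).
#' @param uni_threshold,bi_threshold region ZFst cutoffs.
#' @param zfst_summary `"weighted_mean"` (default) or `"max"`.
#' @return `common_regions` with added `zfst_chd_eud`, per-group
#'   `h12_*` columns, `h12_missing` and `classification`.
#' @export
split_uni_bi <- function(common_regions, zfst_chd_eud_rows, h12_summary,
                         uni_threshold = -1, bi_threshold = 2,
                         zfst_summary = c("weighted_mean", "max")) {
  zfst_summary <- match.arg(zfst_summary)
  z <- region_zfst(common_regions, zfst_chd_eud_rows, zfst_summary)
  h <- h12_wide(h12_summary, common_regions)
  out <- common_regions |>
    dplyr::mutate(zfst_chd_eud = z) |>
    dplyr::bind_cols(h)
  out |>
    dplyr::mutate(
      h12_missing = is.na(.data$h12_chd) | is.na(.data$h12_chw) |
        is.na(.data$h12_eud) | is.na(.data$h12_euw),
      h12_pass = !.data$h12_missing &
        .data$h12_chd > .data$h12_chw & .data$h12_eud > .data$h12_euw,
      classification = dplyr::case_when(
        .data$h12_missing ~ "common",
        !is.na(.data$zfst_chd_eud) &
          .data$zfst_chd_eud < uni_threshold & .data$h12_pass ~
          "unidirectional",
        !is.na(.data$zfst_chd_eud) &
          .data$zfst_chd_eud > bi_threshold & .data$h12_pass ~
          "bidirectional",
        TRUE ~ "common"
      ))
}

# length-weighted mean (or max) of member-window zfst over a region.
# Member windows are those with the majority (> half) of their span
# inside the region extent, so a region does not inherit the signal of
# windows that mostly cover its flanks; if no window qualifies (very
# narrow extents) all overlapping windows are used.
region_zfst <- function(regions, rows, summary = "weighted_mean") {
  purrr::pmap_dbl(regions[c("contig", "start", "end")],
                  function(contig, start, end) {
    ov <- pmin(rows$end, end) - pmax(rows$start, start)
    sel <- rows$contig == contig & ov > 0
    member <- sel & ov > (rows$end - rows$start) / 2
    if (!any(member)) member <- sel          # extent narrower than half
    member <- member & !is.na(rows$zfst)
    if (!any(member)) return(NA_real_)
    z <- rows$zfst[member]
    if (summary == "max") return(max(z))
    w <- ov[member]
    sum(w * z) / sum(w)
  })
}

# pivot a region_h12 summary to one row per region with h12_<role>
h12_wide <- function(h12_summary, regions) {
  role <- if ("role" %in% names(h12_summary)) {
    h12_summary$role
  } else {
    tolower(h12_summary$group)
  }
  h12_summary <- dplyr::mutate(h12_summary, role = tolower(role))
  bad <- setdiff(unique(h12_summary$role),
                 c("chw", "chd", "euw", "eud", "ap", "out"))
  if (length(bad) > 0) {
    stop("h12 summary groups must map to roles chw/chd/euw/eud ",
         "(got: ", paste(bad, collapse = ", "),
         "); add a 'role' column", call. = FALSE)
  }
  wide <- h12_summary |>
    dplyr::select("contig", "start", "end", "role", "h12") |>
    tidyr::pivot_wider(names_from = "role", values_from = "h12",
                       names_prefix = "h12_")
  for (col in paste0("h12_", c("chw", "chd", "euw", "eud"))) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  regions |>
    dplyr::select("contig", "start", "end") |>
    dplyr::left_join(wide, by = c("contig", "start", "end")) |>
    dplyr::select(dplyr::starts_with("h12_"))
}

#' Assign genes to regions by span distance
#'
#' A gene is assigned to a region iff the minimal distance between the
#' two spans is at most `max_dist` (0 means overlap; the comparison is
#' `<=`, so a gene exactly at `max_dist` is assigned). Distances are
#' span-to-span, not TSS-based.
#'
#' @param regions tibble (`contig`, `start`, `end`).
#' @param genes tibble from [read_gene_annotation()].
#' @param max_dist maximum gap in bp (default 20000).
#' @return tibble with one row per (region, assigned gene):
#'   region columns plus `gene_id`, `distance`.
#' @export
annotate_genes <- function(regions, genes, max_dist = 20000) {
  if (nrow(regions) == 0 || nrow(genes) == 0) {
    return(tibble::tibble(contig = character(), start = numeric(),
                          end = numeric(), gene_id = character(),
                          distance = numeric()))
  }
  dplyr::inner_join(
    dplyr::select(regions, "contig", "start", "end"),
    dplyr::select(genes, "contig", "gene_id",
                  g_start = "start", g_end = "end"),
    by = "contig", relationship = "many-to-many") |>
    dplyr::mutate(distance = span_distance(.data$start, .data$end,
                                           .data$g_start, .data$g_end)) |>
    dplyr::filter(.data$distance <= max_dist) |>
    dplyr::select("contig", "start", "end", "gene_id", "distance")
}

# minimal gap between two 0-based half-open spans (0 if overlapping)
span_distance <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1 - e2, s2 - e1))
}

#' Enrichment of differentially expressed genes in a distance zone
#' around regions
#'
#' Classifies every gene as "in zone" iff its minimal span distance to
#' any listed region lies in `[dmin, dmax]` (a gene overlapping a
#' region has distance 0 and is NOT in zone for `dmin > 0`), then
#' tests the 2x2 table (DEG status x in-zone status) with a Pearson
#' chi-squared test on 1 df, without continuity correction by default.
#' A degenerate margin (e.g. all genes in zone) gives an undefined
#' test, flagged rather than raised.
#'
#' @param regions tibble (`contig`, `start`, `end`).
#' @param genes tibble from [read_gene_annotation()].
#' @param deg_flags logical vector (or tibble with `gene_id`, `deg`)
#'   flagging differentially expressed genes; every gene needs a flag.
#' @param dmin,dmax zone bounds in bp (defaults 20000 and 250000).
#' @param correct apply Yates continuity correction (default FALSE).
#' @return one-row tibble: `n_genes`, `n_deg`, `count_in_zone`,
#'   `deg_in_zone`, `chi2`, `p`, `degenerate`.
#' @export
deg_proximity_enrichment <- function(regions, genes, deg_flags,
                                     dmin = 20000, dmax = 250000,
                                     correct = FALSE) {
  if (is.data.frame(deg_flags)) {
    flags <- deg_flags$deg[match(genes$gene_id, deg_flags$gene_id)]
  } else {
    flags <- deg_flags
  }
  if (length(flags) != nrow(genes) || anyNA(flags)) {
    stop("every gene needs a DEG flag", call. = FALSE)
  }
  d <- purrr::pmap_dbl(genes[c("contig", "start", "end")],
                       function(contig, start, end) {
    sel <- regions$contig == contig
    if (!any(sel)) return(Inf)
    min(span_distance(regions$start[sel], regions$end[sel], start, end))
  })
  in_zone <- d >= dmin & d <= dmax
  tab <- table(factor(flags, c(TRUE, FALSE)),
               factor(in_zone, c(TRUE, FALSE)))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    chi2 <- NA_real_
    p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    chi2 <- unname(ct$statistic)
    p <- ct$p.value
  }
  tibble::tibble(n_genes = nrow(genes), n_deg = sum(flags),
                 count_in_zone = sum(in_zone),
                 deg_in_zone = sum(flags & in_zone),
                 chi2 = chi2, p = p, degenerate = degenerate)
}
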