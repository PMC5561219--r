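#' Assemble a pipeline configuration
#'
#' Collects every knob of the scan in one validated list. Inputs may
#' be given either as paths (`vcf`, `popmap`, `contigs`) or in memory
#' (`dataset`, `contigs`); in-memory inputs win. `roles` maps the four
#' core analysis roles (plus the optional ancient sample) to the group
#' labels used in the popmap.
#'
#' @param dataset optional [geno_set()] (skips VCF reading).
#' @param vcf,popmap input paths (used when `dataset` is NULL).
#' @param contigs tibble (`contig`, `length`) or path to a
#'   `contig<TAB>length` TSV; defaults to the last variant position
#'   per contig.
#' @param gff optional gene annotation path or tibble.
#' @param deg optional DEG flag table (tibble or TSV path with
#'   columns `gene_id`, `deg`).
#' @param outdir optional output directory; when set, all TSV/BED/JSON
#'   artifacts are written there.
#' @param roles named character vector mapping roles `chw`, `chd`,
#'   `euw`, `eud` (and optionally `ap`) to group labels.
#' @param window_size,window_step Fst window grid in bp (defaults
#'   20000 / 10000).
#' @param min_snps low-SNP window cutoff (default 10).
#' @param z_threshold candidate-window ZFst cutoff (default 2).
#' @param uni_threshold,bi_threshold region-level CHD-vs-EUD ZFst
#'   cutoffs (defaults -1 and 2).
#' @param n_perm,perm_p_max,perm_rule permutation settings (defaults
#'   1000, 0.01, `"max"`).
#' @param h12_window_snps,h12_step_snps,h12_reps H12 scan settings
#'   (defaults 50, 10, 10).
#' @param ancient_margin identity-score margin (default 0.1).
#' @param gene_dist gene-to-region assignment distance in bp
#'   (default 20000).
#' @param deg_dmin,deg_dmax DEG proximity zone in bp (defaults 20000,
#'   250000).
#' @param tajima compute per-group Tajima's D in the scan
#'   (default TRUE).
#' @param seed master seed for permutations and H12 subsampling.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(dataset = NULL, vcf = NULL, popmap = NULL,
                            contigs = NULL, gff = NULL, deg = NULL,
                            outdir = NULL,
                            roles = c(chw = "CHW", chd = "CHD",
                                      euw = "EUW", eud = "EUD",
                                      ap = "AP"),
                            window_size = 20000, window_step = 10000,
                            min_snps = 10, z_threshold = 2,
                            uni_threshold = -1, bi_threshold = 2,
                            n_perm = 1000, perm_p_max = 0.01,
                            perm_rule = "max",
                            h12_window_snps = 50, h12_step_snps = 10,
                            h12_reps = 10, ancient_margin = 0.1,
                            gene_dist = 20000, deg_dmin = 20000,
                            deg_dmax = 250000, tajima = TRUE,
                            seed = 1) {
  if (is.null(dataset) && (is.null(vcf) || is.null(popmap))) {
    stop("provide either `dataset` or both `vcf` and `popmap`",
         call. = FALSE)
  }
  core <- c("chw", "chd", "euw", "eud")
  if (!all(core %in% names(roles))) {
    stop("roles must cover chw, chd, euw, eud", call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full selection scan
#'
#' Executes, in order: windowed Weir-Cockerham Fst for the two
#' domestic-vs-wild contrasts and the domestic-vs-domestic contrast;
#' genome-wide Z-transformation; candidate windows (`ZFst >
#' z_threshold`) merged into regions per domestic scan; intersection
#' into shared ("common") regions; a label-permutation filter
#' (`p < perm_p_max`); H12 region summaries (with sample-size-matched
#' subsampling for the larger domestic groups); the
#' unidirectional/bidirectional split; ancient-genome identity-score
#' classification of unidirectional regions; and optional gene
#' annotation and DEG proximity enrichment. When `config$outdir` is
#' set, all artifacts (TSV/BED plus a JSON run summary) are written.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `duosweep_run`: a list of result tibbles
#'   (`scan`, `regions_chd`, `regions_eud`, `common`, `regions`,
#'   `h12_regions`, `gene_hits`, `enrichment`) plus the `summary`
#'   list. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  gs <- cfg$dataset
  if (is.null(gs)) gs <- read_genotypes(cfg$vcf, cfg$popmap)
  contigs <- cfg$contigs
  if (is.character(contigs)) {
    contigs <- read_tsv_commented(contigs, c("contig", "length"))
  }
  if (is.null(contigs)) {
    contigs <- gs$variants |>
      dplyr::group_by(contig = .data$contig) |>
      dplyr::summarise(length = max(.data$pos), .groups = "drop")
  }
  r <- as.list(cfg$roles)
  present <- unique(gs$samples$group)
  for (role in c("chw", "chd", "euw", "eud")) {
    if (!r[[role]] %in% present) {
      stop("group '", r[[role]], "' (role ", role,
           ") absent from dataset", call. = FALSE)
    }
  }
  has_ap <- !is.null(r$ap) && r$ap %in% present

  windows <- make_windows(contigs, cfg$window_size, cfg$window_step)
  contrasts <- list(c(r$chd, r$chw), c(r$eud, r$euw), c(r$chd, r$eud))
  scan <- window_scan(gs, contrasts, windows, min_snps = cfg$min_snps,
                      tajima = cfg$tajima)
  scan_of <- function(a, b) {
    dplyr::filter(scan, .data$group_a == a, .data$group_b == b)
  }

  regions_chd <- scan_of(r$chd, r$chw) |>
    call_candidate_windows(cfg$z_threshold) |>
    merge_windows_to_regions()
  regions_eud <- scan_of(r$eud, r$euw) |>
    call_candidate_windows(cfg$z_threshold) |>
    merge_windows_to_regions()
  common <- intersect_common(regions_chd, regions_eud)

  if (nrow(common) > 0) {
    perm <- purrr::map_dfr(seq_len(nrow(common)), function(i) {
      permutation_test(gs, common[i, ], contrasts[1:2],
                       n_perm = cfg$n_perm,
                       seed = (cfg$seed * 131L + i) %% 2147483647L,
                       rule = cfg$perm_rule)
    })
    common <- dplyr::bind_cols(common,
                               perm[c("n_exceed", "n_perm", "p")]) |>
      dplyr::mutate(perm_pass = .data$p < cfg$perm_p_max)
  } else {
    common <- dplyr::mutate(common, n_exceed = integer(), n_perm = integer(),
                            p = numeric(), perm_pass = logical())
  }
  passing <- dplyr::filter(common, .data$perm_pass)

  # H12: plain scan for wild groups, size-matched subsampling for the
  # domestic groups when they are larger than their wild counterpart
  h12_group <- function(group, wild_size, seed_off) {
    n <- sum(gs$samples$group == group)
    if (n > wild_size) {
      h12_subsampled(gs, group, wild_size, reps = cfg$h12_reps,
                     seed = (cfg$seed * 977L + seed_off) %% 2147483647L,
                     window_snps = cfg$h12_window_snps,
                     step_snps = cfg$h12_step_snps) |>
        dplyr::select(-"reps")
    } else {
      suppressMessages(h12_scan(gs, group, cfg$h12_window_snps,
                                cfg$h12_step_snps))
    }
  }
  n_chw <- sum(gs$samples$group == r$chw)
  n_euw <- sum(gs$samples$group == r$euw)
  h12_rows <- dplyr::bind_rows(
    suppressMessages(h12_scan(gs, r$chw, cfg$h12_window_snps,
                              cfg$h12_step_snps)),
    suppressMessages(h12_scan(gs, r$euw, cfg$h12_window_snps,
                              cfg$h12_step_snps)),
    h12_group(r$chd, n_chw, 1L),
    h12_group(r$eud, n_euw, 2L))
  role_of <- stats::setNames(names(unlist(r)), unlist(r))
  h12_regions <- if (nrow(passing) > 0) {
    region_h12(h12_rows, passing) |>
      dplyr::mutate(role = unname(role_of[.data$group]))
  } else {
    tibble::tibble(contig = character(), start = numeric(),
                   end = numeric(), group = character(), h12 = numeric(),
                   n_windows = integer(), role = character())
  }

  regions <- if (nrow(passing) > 0) {
    split_uni_bi(passing, scan_of(r$chd, r$eud), h12_regions,
                 uni_threshold = cfg$uni_threshold,
                 bi_threshold = cfg$bi_threshold)
  } else {
    dplyr::mutate(passing, zfst_chd_eud = numeric(),
                  h12_missing = logical(), h12_pass = logical(),
                  classification = character())
  }

  # ancient-genome identity-score classification of the unidirectional
  # regions
  regions$ancient_call <- "not_applicable"
  regions$is_ap_chd <- NA_real_
  regions$is_ap_euw <- NA_real_
  uni <- regions$classification == "unidirectional"
  if (has_ap && any(uni)) {
    is_chd <- identity_score_window(gs, r$ap, r$chd, windows)
    is_euw <- identity_score_window(gs, r$ap, r$euw, windows)
    anc <- classify_ancient(
      regions[uni, c("contig", "start", "end")],
      region_identity_score(is_chd, regions[uni, ]),
      region_identity_score(is_euw, regions[uni, ]),
      margin = cfg$ancient_margin)
    regions$is_ap_chd[uni] <- anc$is_ap_chd
    regions$is_ap_euw[uni] <- anc$is_ap_euw
    regions$ancient_call[uni] <- anc$ancient_call
  }

  genes <- cfg$gff
  if (is.character(genes)) genes <- read_gene_annotation(genes)
  gene_hits <- NULL
  enrichment <- NULL
  if (!is.null(genes)) {
    gene_hits <- annotate_genes(regions, genes, max_dist = cfg$gene_dist)
    deg <- cfg$deg
    if (is.character(deg)) {
      deg <- read_tsv_commented(deg, c("gene_id", "deg")) |>
        dplyr::mutate(deg = as.logical(.data$deg))
    }
    if (!is.null(deg)) {
      bi <- dplyr::filter(regions, .data$classification == "bidirectional")
      enrichment <- deg_proximity_enrichment(bi, genes, deg,
                                             dmin = cfg$deg_dmin,
                                             dmax = cfg$deg_dmax)
    }
  }

  summary <- list(
    package = "duosweep",
    version = as.character(utils::packageVersion("duosweep")),
    seed = cfg$seed,
    parameters = cfg[c("window_size", "window_step", "min_snps",
                       "z_threshold", "uni_threshold", "bi_threshold",
                       "n_perm", "perm_p_max", "perm_rule",
                       "h12_window_snps", "h12_step_snps", "h12_reps",
                       "ancient_margin", "gene_dist")],
    counts = list(
      n_windows = nrow(windows),
      n_candidate_windows_chd = nrow(call_candidate_windows(
        scan_of(r$chd, r$chw), cfg$z_threshold)),
      n_candidate_windows_eud = nrow(call_candidate_windows(
        scan_of(r$eud, r$euw), cfg$z_threshold)),
      n_regions_chd = nrow(regions_chd),
      n_regions_eud = nrow(regions_eud),
      n_common = nrow(common),
      n_perm_pass = nrow(passing),
      n_unidirectional = sum(regions$classification == "unidirectional"),
      n_bidirectional = sum(regions$classification == "bidirectional"),
      n_common_unsplit = sum(regions$classification == "common"),
      ancient_calls = as.list(table(regions$ancient_call[uni]))
    )
  )

  run <- structure(
    list(scan = scan, windows = windows, regions_chd = regions_chd,
         regions_eud = regions_eud, common = common, regions = regions,
         h12_regions = h12_regions, gene_hits = gene_hits,
         enrichment = enrichment, summary = summary, roles = r,
         config = cfg),
    class = "duosweep_run")
  if (!is.null(cfg$outdir)) write_run(run, cfg$outdir)
  run
}

# write all artifacts of a run to a directory
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  for (ct in unique(run$scan[c("group_a", "group_b")] |>
                      purrr::pmap_chr(paste, sep = "_vs_"))) {
    parts <- strsplit(ct, "_vs_")[[1]]
    write_tsv_commented(
      dplyr::filter(run$scan, .data$group_a == parts[1],
                    .data$group_b == parts[2]),
      p(paste0("scan_", ct, ".tsv")))
  }
  write_tsv_commented(run$common, p("common_regions.tsv"))
  write_tsv_commented(run$regions, p("regions.tsv"))
  write_regions_bed(run$regions, p("regions.bed"))
  write_tsv_commented(run$h12_regions, p("h12_regions.tsv"))
  if (!is.null(run$gene_hits)) {
    write_tsv_commented(run$gene_hits, p("gene_hits.tsv"))
  }
  if (!is.null(run$enrichment)) {
    write_tsv_commented(run$enrichment, p("deg_enrichment.tsv"))
  }
  jsonlite::write_json(run$summary, p("run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.duosweep_run <- function(x, ...) {
  cts <- x$summary$counts
  cat("<duosweep_run>\n")
  cat("  windows scanned:        ", cts$n_windows, "\n")
  cat("  candidate regions CHD:  ", cts$n_regions_chd, "\n")
  cat("  candidate regions EUD:  ", cts$n_regions_eud, "\n")
  cat("  shared (common):        ", cts$n_common,
      " (", cts$n_perm_pass, " pass permutation)\n", sep = "")
  cat("  unidirectional:         ", cts$n_unidirectional, "\n")
  cat("  bidirectional:          ", cts$n_bidirectional, "\n")
  if (length(cts$ancient_calls) > 0) {
    cat("  ancient calls:          ",
        paste(names(cts$ancient_calls), unlist(cts$ancient_calls),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy the classified regions of a run
#'
#' @param x a `duosweep_run`.
#' @param ... unused.
#' @return tibble of classified regions (one row per
#'   permutation-passing common region).
#' @export
tidy.duosweep_run <- function(x, ...) {
  tibble::as_tibble(x$regions)
}

#' One-row summary of a run
#'
#' @param x a `duosweep_run`.
#' @param ... unused.
#' @return one-row tibble of headline counts.
#' @export
glance.duosweep_run <- function(x, ...) {
  cts <- x$summary$counts
  tibble::tibble(
    n_windows = cts$n_windows,
    n_regions_chd = cts$n_regions_chd,
    n_regions_eud = cts$n_regions_eud,
    n_common = cts$n_common,
    n_perm_pass = cts$n_perm_pass,
    n_unidirectional = cts$n_unidirectional,
    n_bidirectional = cts$n_bidirectional,
    seed = x$summary$seed
  )
}
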