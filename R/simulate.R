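#' Configuration for the founder-haplotype cohort simulator
#'
#' The simulator emulates the cohort structure of a two-center
#' domestication study: two wild populations (CHW, EUW) diverged from
#' a common ancestor, two domestic populations (CHD, EUD) derived from
#' their local wild populations, and a single ancient sample (AP) with
#' heavy missingness. Each genomic block of `region_length` bp carries
#' its own pool of `founder_haplotypes` haplotypes; group-level
#' founder frequencies drift along each branch via a Balding-Nichols
#' style Dirichlet reparameterization, and selection scenarios raise a
#' favoured founder to `sweep_frequency` in the swept groups.
#'
#' Scenarios:
#' * `neutral` — drift only;
#' * `uni_introgression` — one CHW-origin founder swept in BOTH CHD
#'   and EUD; the ancient sample draws from the (pre-introgression)
#'   EUW pool;
#' * `uni_preintrogression` — the same sweep, but the ancient sample
#'   draws from the swept domestic pool (selection predates it);
#' * `bidirectional` — two distinct founders swept to opposite
#'   near-fixation in CHD and EUD; wild groups stay intermediate.
#'
#' @param n_contigs number of contigs (default 2).
#' @param contig_length contig length in bp (default 2e6).
#' @param n_regions named counts per scenario (defaults: 50 neutral,
#'   10 of each sweep scenario).
#' @param region_length block length in bp (default 20000).
#' @param snp_density variants per bp (default 1/200).
#' @param samples_per_group named counts (defaults 30 per core group,
#'   1 AP).
#' @param founder_haplotypes founder pool size K per block
#'   (default 16).
#' @param background_divergence per-branch drift parameter theta in
#'   `[0, 1)`: either a single value or `c(wild = ..., domestic =
#'   ...)`. Defaults `c(wild = 0.25, domestic = 0.03)`.
#' @param sweep_frequency frequency of the favoured founder in swept
#'   groups, in `(0.8, 1]` (default 0.98).
#' @param ancient_missing_rate per-site missing probability for AP
#'   (default 0.3).
#' @param seed integer seed; identical seed + config gives
#'   byte-identical outputs.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_contigs = 2,
                       contig_length = 2e6,
                       n_regions = c(neutral = 50,
                                     uni_introgression = 10,
                                     uni_preintrogression = 10,
                                     bidirectional = 10),
                       region_length = 20000,
                       snp_density = 1 / 200,
                       samples_per_group = c(CHW = 30, CHD = 30,
                                             EUW = 30, EUD = 30, AP = 1),
                       founder_haplotypes = 16,
                       background_divergence = c(wild = 0.25,
                                                 domestic = 0.03),
                       sweep_frequency = 0.98,
                       ancient_missing_rate = 0.3,
                       seed = 1) {
  if (length(background_divergence) == 1) {
    background_divergence <- c(wild = unname(background_divergence),
                               domestic = unname(background_divergence))
  }
  stopifnot(
    n_contigs >= 1, contig_length > 0, region_length > 0,
    snp_density > 0, founder_haplotypes >= 2,
    all(background_divergence >= 0), all(background_divergence < 1),
    sweep_frequency > 0.8, sweep_frequency <= 1,
    ancient_missing_rate >= 0, ancient_missing_rate <= 1,
    all(n_regions >= 0), all(samples_per_group >= 1)
  )
  scen <- c("neutral", "uni_introgression", "uni_preintrogression",
            "bidirectional")
  if (!all(names(n_regions) %in% scen)) {
    stop("unknown scenario in n_regions", call. = FALSE)
  }
  core <- c("CHW", "CHD", "EUW", "EUD")
  if (!all(core %in% names(samples_per_group))) {
    stop("samples_per_group must cover CHW, CHD, EUW, EUD", call. = FALSE)
  }
  blocks_per_contig <- floor(contig_length / region_length)
  if (sum(n_regions) > n_contigs * blocks_per_contig) {
    stop("region budget (", sum(n_regions), ") exceeds contig capacity (",
         n_contigs * blocks_per_contig, " blocks)", call. = FALSE)
  }
  structure(
    list(n_contigs = n_contigs, contig_length = contig_length,
         n_regions = n_regions, region_length = region_length,
         snp_density = snp_density,
         samples_per_group = samples_per_group,
         founder_haplotypes = founder_haplotypes,
         background_divergence = background_divergence,
         sweep_frequency = sweep_frequency,
         ancient_missing_rate = ancient_missing_rate,
         seed = as.integer(seed)),
    class = "sim_config")
}

# Dirichlet draw; components with alpha = 0 stay exactly 0
rdirichlet1 <- function(alpha) {
  g <- ifelse(alpha > 0, stats::rgamma(length(alpha), shape = alpha), 0)
  if (sum(g) == 0) {
    # pathological underflow: fall back to the mean
    return(alpha / sum(alpha))
  }
  g / sum(g)
}

# Balding-Nichols style drift of a founder-frequency vector
drift_freqs <- function(f, theta) {
  if (theta == 0) return(f)
  rdirichlet1(f * (1 - theta) / theta)
}

# raise one founder to freq `sf`, rescaling the rest proportionally
sweep_freqs <- function(f, favoured, sf) {
  out <- f
  rest <- sum(f[-favoured])
  if (rest == 0) {
    out[] <- 0
    out[favoured] <- 1
    return(out)
  }
  out[-favoured] <- f[-favoured] * (1 - sf) / rest
  out[favoured] <- sf
  out
}

#' Simulate a phased cohort with known selection scenarios
#'
#' See [sim_config()] for the generative model. All randomness flows
#' through seeds derived from `config$seed` per block, so results are
#' reproducible and independent of evaluation order.
#'
#' @param config a [sim_config()].
#' @return list with elements `dataset` (a [geno_set()]), `truth`
#'   (tibble: `contig`, `start`, `end`, `scenario`, `chd_founder`,
#'   `eud_founder`) and `contigs` (tibble: `contig`, `length`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  bpc <- floor(cfg$contig_length / cfg$region_length)
  n_blocks <- cfg$n_contigs * bpc
  scen_vec <- withr::with_seed(cfg$seed, {
    v <- rep("background", n_blocks)
    counts <- cfg$n_regions
    n_sweep <- sum(counts[names(counts) != "neutral"])
    n_neutral <- sum(counts[names(counts) == "neutral"])
    contig_of <- (seq_len(n_blocks) - 1) %/% bpc
    # sweep regions are insulated by at least one non-sweep block on
    # each side (selected regions in real genomes are far apart);
    # adjacent sweeps would merge into one candidate region and no
    # longer be independently recoverable
    perm <- sample.int(n_blocks)
    sweep_blocks <- integer(0)
    excluded <- logical(n_blocks)
    for (b in perm) {
      if (length(sweep_blocks) == n_sweep) break
      if (excluded[b]) next
      sweep_blocks <- c(sweep_blocks, b)
      excluded[b] <- TRUE
      for (nb in c(b - 1L, b + 1L)) {
        if (nb >= 1 && nb <= n_blocks && contig_of[nb] == contig_of[b]) {
          excluded[nb] <- TRUE
        }
      }
    }
    if (length(sweep_blocks) < n_sweep) {
      stop("cannot place ", n_sweep, " non-adjacent sweep regions in ",
           n_blocks, " blocks; reduce the region budget", call. = FALSE)
    }
    sweep_names <- rep(names(counts)[names(counts) != "neutral"],
                       counts[names(counts) != "neutral"])
    v[sweep_blocks] <- sample(sweep_names)
    free <- setdiff(seq_len(n_blocks), sweep_blocks)
    v[sample(free, n_neutral)] <- "neutral"
    v
  })
  groups <- names(cfg$samples_per_group)
  n_by_group <- cfg$samples_per_group
  sample_ids <- unlist(purrr::map(groups, function(g) {
    paste0(g, "_", seq_len(n_by_group[[g]]))
  }))
  sample_groups <- rep(groups, n_by_group)
  n_samp <- length(sample_ids)
  has_ap <- "AP" %in% groups

  th_w <- cfg$background_divergence[["wild"]]
  th_d <- cfg$background_divergence[["domestic"]]
  K <- cfg$founder_haplotypes
  S <- max(1L, round(cfg$region_length * cfg$snp_density))

  blocks <- purrr::map(seq_len(n_blocks), function(b) {
    contig_i <- (b - 1) %/% bpc + 1
    block_start <- ((b - 1) %% bpc) * cfg$region_length
    block_seed <- (cfg$seed %% 100003L) * 10007L + b
    withr::with_seed(block_seed, {
      pos <- block_start + sort(sample.int(cfg$region_length, S))
      founders <- matrix(0L, K, S)
      for (s in seq_len(S)) {
        p_anc <- stats::runif(1, 0.2, 0.8)
        al <- stats::rbinom(K, 1, p_anc)
        if (length(unique(al)) == 1) al[sample.int(K, 1)] <- 1L - al[1]
        founders[, s] <- al
      }
      f0 <- rdirichlet1(rep(1, K))
      f_chw <- drift_freqs(f0, th_w)
      f_euw <- drift_freqs(f0, th_w)
      f_chd <- drift_freqs(f_chw, th_d)
      f_eud <- drift_freqs(f_euw, th_d)

      scen <- scen_vec[b]
      chd_founder <- NA_integer_
      eud_founder <- NA_integer_
      # the favoured founder is standing variation at moderate
      # frequency (~0.05) in its source wild pool and rare in the opposite
      # wild pool (a geographically localized haplotype), so a sweep
      # produces a marked frequency shift rather than reinforcing a
      # Eurasian consensus haplotype
      standing <- function(f_src, f_other, exclude = integer(0)) {
        score <- abs(f_src - 0.05) + f_other
        score[f_src == 0] <- Inf
        score[exclude] <- Inf
        which.min(score)
      }
      if (scen %in% c("uni_introgression", "uni_preintrogression")) {
        fav <- standing(f_chw, f_euw)      # CHW-origin founder
        f_chd <- sweep_freqs(f_chd, fav, cfg$sweep_frequency)
        f_eud <- sweep_freqs(f_eud, fav, cfg$sweep_frequency)
        chd_founder <- eud_founder <- fav
      } else if (scen == "bidirectional") {
        fav_a <- standing(f_chw, f_euw)
        fav_b <- standing(f_euw, f_chw, exclude = fav_a)
        f_chd <- sweep_freqs(f_chd, fav_a, cfg$sweep_frequency)
        f_eud <- sweep_freqs(f_eud, fav_b, cfg$sweep_frequency)
        chd_founder <- fav_a
        eud_founder <- fav_b
      }
      pool_of <- list(CHW = f_chw, CHD = f_chd, EUW = f_euw, EUD = f_eud,
                      OUT = f0)
      pool_of$AP <- if (scen == "uni_preintrogression") f_eud else f_euw

      a1 <- matrix(NA_integer_, S, n_samp)
      a2 <- matrix(NA_integer_, S, n_samp)
      for (g in groups) {
        cols <- which(sample_groups == g)
        pool <- pool_of[[g]]
        ids1 <- sample.int(K, length(cols), replace = TRUE, prob = pool)
        ids2 <- sample.int(K, length(cols), replace = TRUE, prob = pool)
        a1[, cols] <- t(founders[ids1, , drop = FALSE])
        a2[, cols] <- t(founders[ids2, , drop = FALSE])
      }
      if (has_ap && cfg$ancient_missing_rate > 0) {
        ap_cols <- which(sample_groups == "AP")
        miss <- stats::runif(S) < cfg$ancient_missing_rate
        a1[miss, ap_cols] <- NA_integer_
        a2[miss, ap_cols] <- NA_integer_
      }
      list(contig = paste0("contig", contig_i), pos = pos,
           a1 = a1, a2 = a2, scenario = scen,
           start = block_start, end = block_start + cfg$region_length,
           chd_founder = chd_founder, eud_founder = eud_founder)
    })
  })

  variants <- tibble::tibble(
    contig = rep(purrr::map_chr(blocks, "contig"), each = S),
    pos = as.integer(unlist(purrr::map(blocks, "pos"))),
    ref = "A", alt = "G")
  a1 <- do.call(rbind, purrr::map(blocks, "a1"))
  a2 <- do.call(rbind, purrr::map(blocks, "a2"))
  samples <- tibble::tibble(sample = sample_ids, group = sample_groups)
  dataset <- geno_set(variants, samples, a1, a2, phased = TRUE)

  truth <- purrr::map_dfr(blocks, function(bl) {
    if (bl$scenario == "background") return(NULL)
    tibble::tibble(contig = bl$contig, start = bl$start, end = bl$end,
                   scenario = bl$scenario,
                   chd_founder = bl$chd_founder,
                   eud_founder = bl$eud_founder)
  })
  contigs <- tibble::tibble(contig = paste0("contig", seq_len(cfg$n_contigs)),
                            length = cfg$contig_length)
  list(dataset = dataset, truth = truth, contigs = contigs)
}

#' Write a simulated cohort as a plain-text fixture set
#'
#' Emits a phased VCF, a popmap TSV, the truth TSV, a contigs TSV and
#' a toy GFF3 with one gene per truth region (placed `gene_offset` bp
#' after the region start, `gene_length` bp long) for proximity tests.
#'
#' @param sim list from [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @param gene_offset offset of each toy gene from its region start in
#'   bp (default 5000; may exceed the region length to place genes
#'   outside).
#' @param gene_length toy gene length in bp (default 1000).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(sim, out_dir, gene_offset = 5000,
                          gene_length = 1000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(out_dir, "cohort.vcf"),
             popmap = file.path(out_dir, "popmap.tsv"),
             truth = file.path(out_dir, "truth.tsv"),
             contigs = file.path(out_dir, "contigs.tsv"),
             gff = file.path(out_dir, "genes.gff3"))
  write_genotypes(sim$dataset, paths[["vcf"]], paths[["popmap"]],
                  contig_lengths = sim$contigs)
  write_tsv_commented(sim$truth, paths[["truth"]])
  write_tsv_commented(sim$contigs, paths[["contigs"]])
  gff <- c("##gff-version 3")
  if (nrow(sim$truth) > 0) {
    g_start0 <- sim$truth$start + gene_offset
    gff <- c(gff, sprintf(
      "%s\tduosweep\tgene\t%d\t%d\t.\t+\t.\tID=gene_%03d;scenario=%s",
      sim$truth$contig, g_start0 + 1L, g_start0 + gene_length,
      seq_len(nrow(sim$truth)), sim$truth$scenario))
  }
  writeLines(gff, paths[["gff"]])
  invisible(paths)
}

#' Read a truth table written by [write_fixture()]
#' @param path truth TSV path.
#' @return tibble.
#' @export
read_truth <- function(path) {
  read_tsv_commented(path, c("contig", "start", "end", "scenario",
                             "chd_founder", "eud_founder"))
}
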