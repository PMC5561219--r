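#' Phased genotype dataset
#'
#' The central container of the package: a biallelic, diploid genotype
#' matrix with per-variant coordinates and per-sample group labels. The
#' two allele matrices `a1` and `a2` hold allele codes (0 = REF,
#' 1 = ALT, `NA` = missing) with variants in rows and samples in
#' columns, so every per-site statistic reduces to row operations.
#'
#' @param variants tibble with columns `contig`, `pos` (1-based, as in
#'   VCF), `ref`, `alt`; positions strictly increasing within a contig.
#' @param samples tibble with columns `sample`, `group`; every sample
#'   belongs to exactly one group.
#' @param a1,a2 integer matrices (variants x samples) of allele codes
#'   0/1/`NA`.
#' @param phased logical matrix of the same shape flagging phased
#'   genotypes, or a single logical recycled to all entries.
#'
#' @return An object of class `geno_set`.
#' @export
geno_set <- function(variants, samples, a1, a2, phased = TRUE) {
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)
  stopifnot(
    all(c("contig", "pos") %in% names(variants)),
    all(c("sample", "group") %in% names(samples)),
    nrow(a1) == nrow(variants), ncol(a1) == nrow(samples),
    identical(dim(a1), dim(a2))
  )
  if (anyDuplicated(samples$sample) > 0) {
    stop("duplicate sample ids in sample table", call. = FALSE)
  }
  bad <- setdiff(stats::na.omit(unique(c(a1, a2))), c(0L, 1L))
  if (length(bad) > 0) {
    stop("allele codes must be 0, 1 or NA (biallelic only)", call. = FALSE)
  }
  ord_ok <- variants |>
    dplyr::group_by(.data$contig) |>
    dplyr::summarise(ok = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(ord_ok$ok)) {
    stop("variant positions must be strictly increasing within each contig",
         call. = FALSE)
  }
  if (is.logical(phased) && length(phased) == 1) {
    phased <- matrix(phased, nrow(a1), ncol(a1))
  }
  structure(
    list(variants = variants, samples = samples,
         a1 = a1, a2 = a2, phased = phased),
    class = "geno_set"
  )
}

#' @export
print.geno_set <- function(x, ...) {
  cat("<geno_set> ", nrow(x$variants), " biallelic SNPs x ",
      nrow(x$samples), " samples\n", sep = "")
  grp <- table(x$samples$group)
  cat("groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  cat("contigs:", paste(unique(x$variants$contig), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_set <- function(x) c(nrow(x$variants), nrow(x$samples))

#' Column indices of the samples in a group
#' @param gs a [geno_set()].
#' @param group group label.
#' @keywords internal
group_cols <- function(gs, group) {
  idx <- which(gs$samples$group == group)
  if (length(idx) == 0) {
    stop("group '", group, "' has no samples", call. = FALSE)
  }
  idx
}

#' Read a phased VCF and a population map into a `geno_set`
#'
#' Only biallelic SNP records are retained; multiallelic and non-SNP
#' records are skipped and their count reported with a message. Missing
#' alleles are preserved as `NA`.
#'
#' @param vcf_path path to a VCF 4.x file (plain text or bgzipped).
#' @param popmap_path path to a two-column TSV (`sample<TAB>group`,
#'   lines starting with `#` ignored). Every sample in the VCF must be
#'   listed.
#' @return A [geno_set()].
#' @export
read_genotypes <- function(vcf_path, popmap_path) {
  if (!file.exists(vcf_path)) {
    stop("VCF not found: ", vcf_path, call. = FALSE)
  }
  popmap <- read_popmap(popmap_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix_m <- vcfR::getFIX(v)
  if (is.null(dim(fix_m))) fix_m <- t(fix_m)   # single-record VCF
  fix <- tibble::as_tibble(fix_m)
  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  is_snp[is.na(is_snp)] <- FALSE
  n_skip <- sum(!is_snp)
  if (n_skip > 0) {
    message("read_genotypes: skipped ", n_skip,
            " multiallelic/non-SNP record(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]

  vcf_samples <- colnames(gt)
  missing_map <- setdiff(vcf_samples, popmap$sample)
  if (length(missing_map) > 0) {
    stop("sample(s) absent from popmap: ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  samples <- popmap[match(vcf_samples, popmap$sample), ]

  a1c <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2c <- substr(gt, 3, 3)
  to_code <- function(ch) {
    out <- suppressWarnings(as.integer(ch))
    dim(out) <- dim(gt)
    out
  }
  a1 <- to_code(a1c)
  a2 <- to_code(a2c)
  phased <- sep == "|"
  phased[is.na(phased)] <- FALSE
  dim(phased) <- dim(gt)

  variants <- tibble::tibble(
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  ord_ok <- variants |>
    dplyr::group_by(.data$contig) |>
    dplyr::summarise(ok = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(ord_ok$ok)) {
    stop("VCF is not coordinate-sorted (or has duplicate positions)",
         call. = FALSE)
  }
  geno_set(variants, samples, a1, a2, phased)
}

#' Read a sample-to-group map
#' @inheritParams read_genotypes
#' @return tibble with columns `sample`, `group`.
#' @export
read_popmap <- function(popmap_path) {
  if (!file.exists(popmap_path)) {
    stop("popmap not found: ", popmap_path, call. = FALSE)
  }
  readr::read_tsv(popmap_path, comment = "#",
                  col_names = c("sample", "group"),
                  col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Write a `geno_set` as a phased plain-text VCF plus popmap
#'
#' Emits a minimal VCF 4.2 with GT-only genotypes (`a|b`, missing as
#' `./.`) and the matching `sample<TAB>group` popmap. The writer is
#' deliberately plain-text so fixtures stay inspectable and diffable.
#'
#' @param gs a [geno_set()].
#' @param vcf_path,popmap_path output paths.
#' @param contig_lengths optional tibble (`contig`, `length`) for
#'   `##contig` header lines.
#' @return `vcf_path`, invisibly.
#' @export
write_genotypes <- function(gs, vcf_path, popmap_path = NULL,
                            contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=duosweep",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          contig_lengths$contig,
                          as.integer(contig_lengths$length)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gs$samples$sample),
                      collapse = "\t"))
  gt <- matrix(paste0(gs$a1, "|", gs$a2), nrow = nrow(gs$a1))
  gt[is.na(gs$a1) | is.na(gs$a2)] <- "./."
  body <- paste(
    gs$variants$contig, gs$variants$pos, ".",
    gs$variants$ref, gs$variants$alt, ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), vcf_path)
  if (!is.null(popmap_path)) {
    writeLines(c("#sample\tgroup",
                 paste(gs$samples$sample, gs$samples$group, sep = "\t")),
               popmap_path)
  }
  invisible(vcf_path)
}
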