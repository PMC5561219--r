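#' Read gene records from a GFF3 file
#'
#' Only features of type `gene` are kept. GFF3 coordinates (1-based,
#' inclusive) are converted to the package-internal 0-based half-open
#' convention, so a gene annotated at `[1001, 2000]` becomes
#' `[1000, 2000)`.
#'
#' @param gff_path path to a GFF3 file.
#' @return tibble with columns `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
read_gene_annotation <- function(gff_path) {
  if (!file.exists(gff_path)) {
    stop("GFF3 not found: ", gff_path, call. = FALSE)
  }
  lines <- readLines(gff_path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  recs <- purrr::map_dfr(which(keep), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      stop("malformed GFF3 line ", i, ": expected 9 tab-separated fields",
           call. = FALSE)
    }
    if (f[3] != "gene") return(NULL)
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1) || end1 < start1) {
      stop("malformed GFF3 line ", i, ": bad coordinates", call. = FALSE)
    }
    id <- stringr::str_match(f[9], "ID=([^;]+)")[, 2]
    if (is.na(id)) id <- f[9]
    tibble::tibble(gene_id = id, contig = f[1],
                   start = start1 - 1L, end = end1, strand = f[7])
  })
  if (nrow(recs) == 0) {
    recs <- tibble::tibble(gene_id = character(), contig = character(),
                           start = integer(), end = integer(),
                           strand = character())
  }
  recs
}

#' Write regions as a BED file
#'
#' BED is 0-based half-open, matching the internal convention; the name
#' column carries the region classification. An empty region set yields
#' a file with just the header comment.
#'
#' @param regions tibble with `contig`, `start`, `end` and optionally
#'   `classification`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  header <- "#contig\tstart\tend\tname"
  if (nrow(regions) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  regions <- dplyr::arrange(regions, .data$contig, .data$start)
  name <- if ("classification" %in% names(regions)) {
    regions$classification
  } else {
    "region"
  }
  writeLines(c(header,
               paste(regions$contig, regions$start, regions$end, name,
                     sep = "\t")),
             path)
  invisible(path)
}

#' Write a tibble as a commented-header TSV
#'
#' All pipeline artifacts share this format: one `#`-prefixed header
#' line naming the columns, then plain TSV rows.
#' @param x tibble.
#' @param path output path.
#' @keywords internal
write_tsv_commented <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(x), collapse = "\t")), con)
  if (nrow(x) > 0) {
    utils::write.table(x, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = "NA")
  }
  invisible(path)
}

read_tsv_commented <- function(path, col_names) {
  readr::read_tsv(path, comment = "#", col_names = col_names,
                  show_col_types = FALSE, progress = FALSE)
}
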