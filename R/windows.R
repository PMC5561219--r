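#' Build the sliding-window grid
#'
#' Windows of `size` bp advancing by `step` bp, 0-based half-open.
#' A window starts at every multiple of `step` smaller than the contig
#' length; trailing windows are truncated at the contig end rather than
#' dropped, so every base pair is covered.
#'
#' @param contig_lengths tibble with columns `contig`, `length`, or a
#'   named numeric vector of lengths.
#' @param size window size in bp (default 20000).
#' @param step step between window starts in bp (default 10000).
#' @return tibble with columns `contig`, `start`, `end`.
#' @examples
#' make_windows(c(chr1 = 50000))
#' @export
make_windows <- function(contig_lengths, size = 20000, step = 10000) {
  stopifnot(size > 0, step > 0)
  if (!is.data.frame(contig_lengths)) {
    contig_lengths <- tibble::tibble(contig = names(contig_lengths),
                                     length = as.numeric(contig_lengths))
  }
  purrr::pmap_dfr(contig_lengths, function(contig, length, ...) {
    starts <- seq(0, length - 1, by = step)
    tibble::tibble(contig = contig, start = starts,
                   end = pmin(starts + size, length))
  })
}

#' Map variants to windows
#'
#' A variant with 1-based position `pos` belongs to window
#' `[start, end)` iff `pos - 1` falls in that interval. Overlapping
#' windows intentionally share variants.
#'
#' @param gs a [geno_set()].
#' @param windows window tibble from [make_windows()].
#' @return list of integer vectors, one per window row, with the
#'   variant row indices of `gs` in that window.
#' @keywords internal
window_site_index <- function(gs, windows) {
  pos0 <- gs$variants$pos - 1L
  by_contig <- split(seq_along(pos0), gs$variants$contig)
  purrr::pmap(windows[c("contig", "start", "end")],
              function(contig, start, end) {
                rows <- by_contig[[contig]]
                if (is.null(rows)) return(integer(0))
                p <- pos0[rows]  # sorted within contig
                lo <- findInterval(start - 0.5, p) + 1L
                hi <- findInterval(end - 0.5, p)
                if (hi < lo) integer(0) else rows[lo:hi]
              })
}
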