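# Independent oracles used across the suite. Each is a deliberately
# plain, scalar, long-hand transcription of the published definitions,
# sharing no code with the package internals it checks.

# --- Weir & Cockerham (1984) two-population components, one site ----
# gA, gB: integer vectors of per-individual allele sums (0/1/2), NA for
# uncalled individuals. Returns c(a, b, c).
wc84_site_oracle <- function(gA, gB) {
  r <- 2
  pops <- list(gA[!is.na(gA)], gB[!is.na(gB)])
  n <- sapply(pops, length)
  if (any(n == 0)) return(c(a = NA, b = NA, c = NA))
  p <- sapply(pops, function(g) sum(g) / (2 * length(g)))
  h <- sapply(pops, function(g) mean(g == 1))
  n_bar <- mean(n)
  if (n_bar <= 1) return(c(a = NA, b = NA, c = NA))
  n_c <- (r * n_bar - sum(n^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n * p) / (r * n_bar)
  s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n * h) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - 1 / (n_bar - 1) *
       (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  c(a = a, b = b, c = cc)
}

# windowed ratio-of-sums Fst from raw allele-sum matrices (sites x
# individuals), looping site by site
wc84_window_oracle <- function(GA, GB) {
  num <- 0
  den <- 0
  for (s in seq_len(nrow(GA))) {
    comp <- wc84_site_oracle(GA[s, ], GB[s, ])
    if (!any(is.na(comp))) {
      num <- num + comp["a"]
      den <- den + sum(comp)
    }
  }
  if (den == 0) NA_real_ else unname(num / den)
}

# --- Tajima (1989) D by full enumeration -----------------------------
# seqs: matrix of 0/1 alleles, rows = chromosomes (complete data)
tajima_oracle <- function(seqs) {
  n <- nrow(seqs)
  S <- sum(apply(seqs, 2, function(x) length(unique(x)) > 1))
  if (S == 0 || n < 4) return(NA_real_)
  diffs <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      diffs <- c(diffs, sum(seqs[i, ] != seqs[j, ]))
    }
  }
  pi <- mean(diffs)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# --- H12 by haplotype-string enumeration -----------------------------
# haps: matrix of 0/1 alleles, rows = haplotypes (complete data)
h12_string_oracle <- function(haps) {
  keys <- apply(haps, 1, paste, collapse = ",")
  p <- sort(as.vector(table(keys)) / length(keys), decreasing = TRUE)
  if (length(p) == 1) p <- c(p, 0)
  (p[1] + p[2])^2 + sum(p[-(1:2)]^2)
}

# --- small random fixtures -------------------------------------------
# a random geno_set on one contig, optionally with missingness
random_geno_set <- function(n_sites = 50, groups = c(A = 6, B = 6),
                            miss_rate = 0, contig = "chr1",
                            spacing = 100) {
  n_samp <- sum(groups)
  a1 <- matrix(rbinom(n_sites * n_samp, 1, 0.5), n_sites, n_samp)
  a2 <- matrix(rbinom(n_sites * n_samp, 1, 0.5), n_sites, n_samp)
  if (miss_rate > 0) {
    m <- matrix(runif(n_sites * n_samp) < miss_rate, n_sites, n_samp)
    a1[m] <- NA_integer_
    a2[m] <- NA_integer_
  }
  geno_set(
    variants = tibble::tibble(
      contig = contig,
      pos = as.integer(seq_len(n_sites) * spacing),
      ref = "A", alt = "G"),
    samples = tibble::tibble(
      sample = paste0("s", seq_len(n_samp)),
      group = rep(names(groups), groups)),
    a1 = a1, a2 = a2, phased = TRUE)
}

# build a geno_set from explicit haplotype matrices per group
# haps: named list group -> list(h1 = matrix, h2 = matrix) with sites
# in rows
geno_from_haps <- function(a1, a2, groups) {
  n_sites <- nrow(a1)
  geno_set(
    variants = tibble::tibble(contig = "chr1",
                              pos = as.integer(seq_len(n_sites) * 10),
                              ref = "A", alt = "G"),
    samples = tibble::tibble(sample = paste0("s", seq_len(ncol(a1))),
                             group = groups),
    a1 = a1, a2 = a2, phased = TRUE)
}
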