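# Brute-force oracles, independent of the implementation paths they check.

withr_local_tempfile <- function() tempfile(fileext = ".txt")

# O(N*M) all-pairs minimum gap between BED intervals (0-based half-open),
# computed with plain arithmetic on vectors -- no GenomicRanges.
oracle_min_gap <- function(a_chr, a_s, a_e, b_chr, b_s, b_e) {
  vapply(seq_along(a_chr), function(i) {
    same <- b_chr == a_chr[i]
    if (!any(same)) return(Inf)
    min(pmax(b_s[same] - a_e[i], a_s[i] - b_e[same], 0))
  }, 0)
}

oracle_fraction_within <- function(anchors, events, cutoff) {
  df <- function(gr) list(chr = as.character(GenomicRanges::seqnames(gr)),
                          s = GenomicRanges::start(gr) - 1L,
                          e = GenomicRanges::end(gr))
  a <- df(anchors); b <- df(events)
  if (!length(a$chr)) return(0)
  if (!length(b$chr)) return(0)
  mean(oracle_min_gap(a$chr, a$s, a$e, b$chr, b$s, b$e) <= cutoff)
}

oracle_colocal_flags <- function(anchors, events, cutoff) {
  df <- function(gr) list(chr = as.character(GenomicRanges::seqnames(gr)),
                          s = GenomicRanges::start(gr) - 1L,
                          e = GenomicRanges::end(gr))
  a <- df(anchors); b <- df(events)
  if (!length(b$chr)) return(rep(FALSE, length(a$chr)))
  oracle_min_gap(a$chr, a$s, a$e, b$chr, b$s, b$e) <= cutoff
}

# brute-force count of in-window (anchor, event-center) pairs
oracle_profile_total <- function(anchors, events, half_window) {
  ac <- interval_center(anchors); ec <- interval_center(events)
  achr <- as.character(GenomicRanges::seqnames(anchors))
  echr <- as.character(GenomicRanges::seqnames(events))
  total <- 0L
  for (i in seq_along(ac)) {
    d <- ec[echr == achr[i]] - ac[i]
    total <- total + sum(abs(d) <= half_window)
  }
  total
}

# exact two-sided Mann-Whitney by enumeration over group assignments,
# written independently of mw_test (works from rank sums of y)
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  cmb <- utils::combn(n1 + n2, n1)
  us <- apply(cmb, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 50000,
                         max_len = 1500) {
  s <- sample.int(max_pos, n, replace = TRUE)
  peak_set(sample(chroms, n, replace = TRUE), s,
           s + sample.int(max_len, n, replace = TRUE),
           score = sample.int(500, n, replace = TRUE))
}

# small deterministic genome + regions for motif tests
tiny_genome_regions <- function(n_regions = 6, region_len = 300,
                                chrom_len = 2e4, gc = 0.5, seed = 11) {
  g <- simulate_genome(c(chr1 = chrom_len), gc = gc, seed = seed)
  starts <- seq(500, by = 2500, length.out = n_regions)
  r <- peak_set(rep("chr1", n_regions), starts, starts + region_len,
                score = 200)
  list(genome = g, regions = r)
}
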