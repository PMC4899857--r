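#' Criteria for selecting a compact, isolated, high-scoring peak subset
#'
#' The selection rule used to pick motif-discovery input regions: peaks
#' shorter than `max_length`, more than `min_isolation` away from any other
#' peak in the set, with score at least `min_score`. Defaults correspond to
#' the published subset rule (< 400 bp, > 1 kb isolation, score >= 150),
#' which yielded 268 regions on the original binding-site set.
#'
#' @param max_length maximum region length in bp, exclusive (default 400).
#' @param min_isolation minimum edge-to-edge gap in bp to the nearest other
#'   peak, exclusive (default 1000).
#' @param min_score minimum peak score, inclusive (default 150).
#' @return a `subset_criteria` list.
#' @export
subset_criteria <- function(max_length = 400L, min_isolation = 1000L,
                            min_score = 150) {
  stopifnot(max_length > 0, min_isolation > 0, min_score > 0)
  structure(list(max_length = as.integer(max_length),
                 min_isolation = as.integer(min_isolation),
                 min_score = as.numeric(min_score)),
            class = "subset_criteria")
}

#' Select the motif-discovery peak subset
#'
#' Applies [subset_criteria()]: length strictly below `max_length`, score
#' `>= min_score`, and edge-to-edge gap to the nearest *other* peak of the
#' full input set strictly above `min_isolation`. Isolation is always
#' evaluated against the complete input set (not the filtered survivors),
#' so the operation is idempotent and order-independent.
#'
#' @param peaks a peak-set `GRanges` with scores.
#' @param criteria a [subset_criteria()].
#' @return the selected subset, a `GRanges`.
#' @export
select_peak_subset <- function(peaks, criteria = subset_criteria()) {
  if (!length(peaks)) return(peaks)
  score <- S4Vectors::mcols(peaks)$score
  if (is.null(score)) stop("peaks carry no scores")
  len <- GenomicRanges::width(peaks)  # equals BED end - start
  iso <- rep(Inf, length(peaks))
  hits <- GenomicRanges::distanceToNearest(peaks, ignore.strand = TRUE)
  iso[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  keep <- len < criteria$max_length &
    score >= criteria$min_score &
    iso > criteria$min_isolation
  peaks[keep]
}

#' Configuration of the randomized genomic null
#'
#' @param n_files number of null replicates (default 3).
#' @param gc_tolerance maximum absolute GC-fraction deviation between a null
#'   region and its matched template region (default 0.02).
#' @param max_attempts_per_region rejection-sampling budget per region.
#' @param max_n_fraction reject candidate loci with more than this fraction
#'   of `N` bases (default 0.10).
#' @param seed integer seed; the whole draw is reproducible from it.
#' @return a `null_config` list.
#' @export
null_config <- function(n_files = 3L, gc_tolerance = 0.02,
                        max_attempts_per_region = 10000L,
                        max_n_fraction = 0.10, seed = 1L) {
  stopifnot(n_files >= 1, gc_tolerance > 0, gc_tolerance < 0.5,
            max_attempts_per_region >= 1)
  structure(list(n_files = as.integer(n_files),
                 gc_tolerance = gc_tolerance,
                 max_attempts_per_region = as.integer(max_attempts_per_region),
                 max_n_fraction = max_n_fraction,
                 seed = as.integer(seed)),
            class = "null_config")
}

#' Length- and GC-matched randomized genomic regions
#'
#' Draws `n_files` sets of random genomic loci matched one-to-one to a
#' template peak set: each null set has exactly the template's multiset of
#' lengths, and every null region's GC fraction lies within
#' `gc_tolerance` of its matched template region's GC. Candidate starts are
#' sampled uniformly (chromosomes weighted by length) and rejected on GC
#' mismatch, on N-content above `max_n_fraction`, or on overlap with any
#' template region. This is the null model against which observed
#' motif-containment fractions are benchmarked.
#'
#' @param template a peak-set `GRanges` (e.g. the 268-region subset).
#' @param genome a `DNAStringSet`.
#' @param cfg a [null_config()].
#' @return a list of `n_files` `GRanges`, each with metadata columns
#'   `name`, `score` (0), `template_gc`, `gc`.
#' @export
generate_matched_random <- function(template, genome, cfg = null_config()) {
  t_gc <- gc_fraction(genome, template)
  t_len <- GenomicRanges::width(template)
  chroms <- names(genome)
  clen <- Biostrings::width(genome)
  # template intervals per chromosome (1-based closed) for overlap rejection
  t_chr <- as.character(GenomicRanges::seqnames(template))
  t_s <- GenomicRanges::start(template); t_e <- GenomicRanges::end(template)
  with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_files), function(f) {
      starts <- integer(length(template))
      chr <- character(length(template))
      gcs <- numeric(length(template))
      for (i in seq_along(template)) {
        L <- t_len[i]
        ok_chrom <- clen >= L
        if (!any(ok_chrom))
          stop("no chromosome long enough for region of length ", L)
        w <- (clen - L + 1) * ok_chrom
        found <- FALSE
        for (att in seq_len(cfg$max_attempts_per_region)) {
          ci <- sample.int(length(chroms), 1L, prob = w)
          s1 <- sample.int(clen[ci] - L + 1L, 1L)  # 1-based start
          same <- t_chr == chroms[ci]
          if (any(t_s[same] <= s1 + L - 1L & t_e[same] >= s1)) next
          sq <- Biostrings::subseq(genome[[ci]], s1, s1 + L - 1L)
          freq <- Biostrings::alphabetFrequency(sq, baseOnly = TRUE)
          acgt <- sum(freq[c("A", "C", "G", "T")])
          if ((L - acgt) / L > cfg$max_n_fraction || acgt == 0L) next
          gc <- sum(freq[c("G", "C")]) / acgt
          if (abs(gc - t_gc[i]) > cfg$gc_tolerance) next
          starts[i] <- s1; chr[i] <- chroms[ci]; gcs[i] <- gc
          found <- TRUE
          break
        }
        if (!found)
          stop("could not GC-match template region ",
               S4Vectors::mcols(template)$name[i] %||% i,
               " (GC ", signif(t_gc[i], 3), ") within ",
               cfg$max_attempts_per_region, " attempts")
      }
      out <- peak_set(chr, starts - 1L, starts - 1L + t_len,
                      name = paste0("rand", f, "_", seq_along(template)),
                      score = 0,
                      label = paste0("random_", f))
      S4Vectors::mcols(out)$template_gc <- t_gc
      S4Vectors::mcols(out)$gc <- gcs
      out
    })
  })
}

# IUPAC nucleotide code -> the set of concrete bases it matches.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.check_iupac <- function(pattern) {
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "")[[1L]]
  if (!length(chars)) stop("empty motif pattern")
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC code(s) in pattern: ", paste(bad, collapse = ", "))
  pattern
}

#' Reverse complement of an IUPAC pattern or sequence
#' @param x character vector of IUPAC nucleotide strings.
#' @return the reverse complement, degenerate codes included.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

# IUPAC pattern -> fixed-length regex of character classes. N in the
# *sequence* matches nothing because classes only contain A/C/G/T.
.iupac_regex <- function(pattern) {
  chars <- strsplit(.check_iupac(pattern), "")[[1L]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Test sequences for motif containment
#'
#' Plain string search: `TRUE` when some position of the sequence matches
#' the fixed-length IUPAC pattern on the forward strand or — when
#' `both_strands` — on the reverse complement. Ambiguity codes are allowed
#' in the pattern only; an `N` in the sequence matches nothing.
#'
#' @param seqs character vector or `DNAStringSet` of subject sequences.
#' @param pattern IUPAC motif string (e.g. a 12-mer).
#' @param both_strands scan the reverse complement too (default `TRUE`).
#' @return logical vector, one per sequence.
#' @examples
#' contains_motif("AAGGAGGGGAAA", "GGAGGGG")           # TRUE
#' contains_motif("CCCCTCC", "GGAGGGG")                # TRUE (minus strand)
#' contains_motif("CCCCTCC", "GGAGGGG", both_strands = FALSE)
#' @export
contains_motif <- function(seqs, pattern, both_strands = TRUE) {
  if (methods::is(seqs, "XStringSet") || methods::is(seqs, "XString"))
    seqs <- as.character(seqs)
  seqs <- toupper(seqs)
  hit <- grepl(.iupac_regex(pattern), seqs, perl = TRUE)
  if (both_strands) {
    pattern_rc <- reverse_complement(pattern)
    hit <- hit | grepl(.iupac_regex(pattern_rc), seqs, perl = TRUE)
  }
  hit
}

#' Fraction of regions containing a motif
#'
#' @param regions a peak-set `GRanges` within genome bounds.
#' @param genome a `DNAStringSet`.
#' @param pattern IUPAC motif string.
#' @param both_strands scan both strands (default `TRUE`).
#' @return a list with `count` and `fraction` (0 with a warning for an
#'   empty region set).
#' @export
motif_fraction <- function(regions, genome, pattern, both_strands = TRUE) {
  if (!length(regions)) {
    warning("empty region set; motif fraction reported as 0")
    return(list(count = 0L, fraction = 0))
  }
  hit <- contains_motif(region_sequences(genome, regions), pattern,
                        both_strands = both_strands)
  list(count = sum(hit), fraction = mean(hit))
}

#' Proximity-stratified motif-enrichment table
#'
#' For the observed region set and each null replicate, reports: the overall
#' motif-containment fraction; the fraction of regions near a replication
#' origin (within `cfg$cutoff_d`); and the motif fractions conditional on
#' being near or not near an origin. This is the table used to argue that a
#' motif tracks protein binding rather than origin activity: observed
#' regions carry the motif at similar rates whether or not they sit at an
#' origin, while GC-matched random loci carry it at background rates.
#'
#' @param regions observed peak-set `GRanges`.
#' @param nulls list of null `GRanges` (e.g. from
#'   [generate_matched_random()]).
#' @param origins replication-origin peak set.
#' @param genome a `DNAStringSet`.
#' @param pattern IUPAC motif string.
#' @param cfg a [proximity_config()].
#' @return a data.frame, one row per set (`observed`, `random_1`, ...), with
#'   counts and fractions for each stratum.
#' @export
enrichment_table <- function(regions, nulls, origins, genome, pattern,
                             cfg = proximity_config()) {
  one <- function(set_name, gr) {
    n <- length(gr)
    hit <- if (n) contains_motif(region_sequences(genome, gr), pattern)
           else logical(0)
    near <- .within_cutoff(gr, origins, cfg)
    frac <- function(num, den) if (den) num / den else NA_real_
    data.frame(
      set = set_name, n_regions = n,
      n_motif = sum(hit), frac_motif = frac(sum(hit), n),
      n_near_origin = sum(near), frac_near_origin = frac(sum(near), n),
      n_motif_near = sum(hit & near),
      frac_motif_near = frac(sum(hit & near), sum(near)),
      n_motif_far = sum(hit & !near),
      frac_motif_far = frac(sum(hit & !near), sum(!near)),
      stringsAsFactors = FALSE
    )
  }
  rows <- c(list(one("observed", regions)),
            lapply(seq_along(nulls), function(i)
              one(paste0("random_", i), nulls[[i]])))
  do.call(rbind, rows)
}
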