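#' Construct a peak set
#'
#' Builds a `GRanges` peak set from BED-style (0-based, half-open)
#' coordinates. This is the in-memory representation used by every analysis
#' function in the package: a `GRanges` with `name` and `score` metadata
#' columns and an optional `label` stored in `metadata(x)$label`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open as in BED
#'   (`start < end`).
#' @param name optional peak names; defaults to `peak_1 ... peak_n`.
#' @param score numeric peak-caller scores (>= 0, finite); recycled.
#' @param strand strand characters (`"+"`, `"-"`, `"*"`); recycled.
#' @param label free-text label for the whole set.
#' @return a `GRanges` with `name` and `score` metadata columns.
#' @examples
#' peak_set("chr1", c(100, 5000), c(200, 5100), score = c(150, 80))
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = 0,
                     strand = "*", label = "") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("start must be >= 0")
  if (any(start >= end)) stop("start must be < end")
  if (any(!is.finite(score)) || any(score < 0))
    stop("scores must be finite and >= 0")
  n <- length(chrom)
  if (is.null(name)) name <- if (n) paste0("peak_", seq_len(n)) else character()
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = rep_len(strand, n)
  )
  S4Vectors::mcols(gr)$name <- as.character(name)
  S4Vectors::mcols(gr)$score <- rep_len(as.numeric(score), n)
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Read peaks from a BED file
#'
#' Reads BED3/BED5/BED6 into a peak-set `GRanges`. Lines starting with
#' `#`, `track` or `browser` are skipped. Column 4 is the peak name
#' (default `.`), column 5 the score (default 0), column 6 the strand.
#' Coordinates are validated as 0-based half-open.
#'
#' @param path path to a tab-separated BED file.
#' @param score_col 1-based column index holding the score; some peak
#'   callers emit the score in a later column (e.g. 7).
#' @param label label recorded in `metadata()$label` (defaults to the
#'   file name).
#' @return a `GRanges` with `name` and `score` metadata columns.
#' @seealso [write_bed()]
#' @export
read_bed <- function(path, score_col = 5L, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(peak_set(character(), integer(), integer(), label = label))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L))
    stop("line ", idx[which(ncols < 3L)[1L]], ": fewer than 3 columns")
  col <- function(j, default) {
    vapply(fields, function(f) if (length(f) >= j) f[[j]] else default, "")
  }
  chrom <- col(1L, NA_character_)
  start <- suppressWarnings(as.numeric(col(2L, NA_character_)))
  end <- suppressWarnings(as.numeric(col(3L, NA_character_)))
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stop("line ", idx[bad[1L]], ": non-integer coordinate")
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop("line ", idx[bad[1L]], ": invalid interval (start >= end or < 0)")
  name <- col(4L, ".")
  score_chr <- col(as.integer(score_col), "")
  score <- suppressWarnings(as.numeric(score_chr))
  score[!nzchar(score_chr) | score_chr == "."] <- 0
  bad <- which(!is.finite(score))
  if (length(bad))
    stop("line ", idx[bad[1L]], ": malformed score ", score_chr[bad[1L]])
  strand <- col(6L, "*")
  strand[!strand %in% c("+", "-")] <- "*"
  peak_set(chrom, start, end, name = name, score = score,
           strand = strand, label = label)
}

#' Write a peak set to BED
#'
#' Emits BED5 (or BED6 when any strand is set), converting back to 0-based
#' half-open coordinates. `read_bed()` followed by `write_bed()` reproduces
#' a well-formed BED5 file byte-identically.
#'
#' @param peaks a peak-set `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  strand <- as.character(GenomicRanges::strand(peaks))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = S4Vectors::mcols(peaks)$name %||% ".",
    score = format(S4Vectors::mcols(peaks)$score %||% 0,
                   trim = TRUE, scientific = FALSE),
    stringsAsFactors = FALSE
  )
  if (any(strand != "*")) df$strand <- ifelse(strand == "*", ".", strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that trims FASTA
#' headers to the first whitespace-delimited token, so sequence names match
#' BED chromosome names.
#'
#' @param path FASTA file (multi-record, wrapped lines allowed).
#' @return a `DNAStringSet` keyed by chromosome name.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome to FASTA
#' @param genome a `DNAStringSet`.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

#' Edge-to-edge gap between two intervals
#'
#' Distance primitives behind all "within d" classification. Overlapping or
#' book-ended intervals have gap 0; intervals on different chromosomes are
#' infinitely far apart. Vectorized over pairs.
#'
#' @param a,b peak-set `GRanges` of equal length (or length 1, recycled).
#' @return numeric vector of gaps in bp (`Inf` across chromosomes).
#' @examples
#' a <- peak_set("chr1", 100, 200)
#' gap_distance(a, peak_set("chr1", 5000, 5100))  # 4800
#' gap_distance(a, peak_set("chr1", 150, 160))    # 0 (overlap)
#' @export
gap_distance <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  # 1-based closed arithmetic: gap = distance between closest edges
  g <- pmax(GenomicRanges::start(b) - GenomicRanges::end(a) - 1L,
            GenomicRanges::start(a) - GenomicRanges::end(b) - 1L,
            0L)
  out <- as.numeric(g)
  out[!same] <- Inf
  out
}

#' Interval centre
#'
#' The centre position used for distance profiles, in 0-based coordinates:
#' `floor((start + end) / 2)` of the BED interval.
#'
#' @param a a peak-set `GRanges`.
#' @return integer vector of 0-based centre positions.
#' @export
interval_center <- function(a) {
  start0 <- GenomicRanges::start(a) - 1L
  as.integer(floor((start0 + GenomicRanges::end(a)) / 2))
}

#' Extract region sequences
#'
#' @param genome a `DNAStringSet`.
#' @param regions a peak-set `GRanges`; must lie within chromosome bounds.
#' @return a `DNAStringSet`, one entry per region.
#' @export
region_sequences <- function(genome, regions) {
  chrom <- as.character(GenomicRanges::seqnames(regions))
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing))
    stop("chromosome(s) not in genome: ", paste(missing, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))[chrom]
  if (any(GenomicRanges::end(regions) > lens) ||
      any(GenomicRanges::start(regions) < 1L))
    stop("region out of chromosome bounds")
  out <- Biostrings::DNAStringSet(vapply(seq_along(regions), function(i) {
    as.character(Biostrings::subseq(genome[[chrom[i]]],
                                    GenomicRanges::start(regions)[i],
                                    GenomicRanges::end(regions)[i]))
  }, ""))
  names(out) <- S4Vectors::mcols(regions)$name %||%
    paste0("region_", seq_along(regions))
  out
}

#' GC fraction of genomic intervals
#'
#' `(#G + #C) / (#A + #C + #G + #T)` with `N` positions excluded from both
#' numerator and denominator. An all-N interval has no defined GC content
#' and raises an error.
#'
#' @param genome a `DNAStringSet`.
#' @param regions a peak-set `GRanges` within chromosome bounds.
#' @return numeric vector in `[0, 1]`.
#' @export
gc_fraction <- function(genome, regions) {
  seqs <- region_sequences(genome, regions)
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  if (any(acgt == 0L))
    stop("degenerate sequence: interval contains no A/C/G/T bases")
  unname(rowSums(freq[, c("G", "C"), drop = FALSE]) / acgt)
}
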