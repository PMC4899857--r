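make_example_peaks <- function() {
  # P1,P2 fail isolation (gap 100); P3 fails score; P4 fails length;
  # P5 passes with score exactly at the threshold
  peak_set(c("chr1", "chr1", "chr1", "chr1", "chr2"),
           c(1000, 1400, 10000, 20000, 5000),
           c(1300, 1500, 10350, 20600, 5200),
           name = paste0("P", 1:5),
           score = c(200, 300, 100, 400, 150))
}

test_that("select_peak_subset applies the length/isolation/score rule", {
  sel <- select_peak_subset(make_example_peaks(), subset_criteria())
  expect_identical(S4Vectors::mcols(sel)$name, "P5")
  empty <- peak_set(character(), integer(), integer())
  expect_length(select_peak_subset(empty), 0L)
  # boundary: length 399 and score exactly 150 are retained
  one <- peak_set("chr1", 1000, 1399, score = 150)
  expect_length(select_peak_subset(one), 1L)
  # boundary: length exactly 400 and score 149.99 are dropped
  expect_length(select_peak_subset(peak_set("chr1", 0, 400, score = 500)), 0L)
  expect_length(select_peak_subset(peak_set("chr1", 0, 399, score = 149.99)),
                0L)
  # isolation boundary: gap exactly 1000 fails the strict rule, 1001 passes
  pair <- function(gap) peak_set(c("chr1", "chr1"), c(0, 300 + gap),
                                 c(300, 600 + gap), score = 150)
  expect_length(select_peak_subset(pair(1000)), 0L)
  expect_length(select_peak_subset(pair(1001)), 2L)
})

test_that("select_peak_subset is idempotent and permutation-invariant", {
  p <- make_example_peaks()
  ref <- sort(S4Vectors::mcols(select_peak_subset(p))$name)
  set.seed(9)
  for (i in 1:100) {
    perm <- p[sample(length(p))]
    expect_identical(sort(S4Vectors::mcols(select_peak_subset(perm))$name),
                     ref)
  }
  sel <- select_peak_subset(p)
  expect_identical(S4Vectors::mcols(select_peak_subset(sel))$name,
                   S4Vectors::mcols(sel)$name)
})

test_that("matched nulls preserve lengths, GC tolerance and determinism", {
  g <- simulate_genome(c(chr1 = 60000, chr2 = 40000), gc = 0.45, seed = 21)
  starts <- c(1000, 5000, 9000, 14000, 20000, 30000)
  template <- peak_set(rep("chr1", 6), starts,
                       starts + c(100, 250, 180, 300, 120, 220), score = 150)
  cfg <- null_config(n_files = 3, gc_tolerance = 0.02, seed = 77)
  nulls <- generate_matched_random(template, g, cfg)
  expect_length(nulls, 3L)
  t_gc <- gc_fraction(g, template)
  for (nl in nulls) {
    expect_identical(sort(GenomicRanges::width(nl)),
                     sort(GenomicRanges::width(template)))
    expect_true(all(abs(gc_fraction(g, nl) - t_gc) <= 0.02 + 1e-12))
    expect_equal(sum(GenomicRanges::countOverlaps(nl, template)), 0L)
  }
  # byte-identical regeneration from the same seed
  again <- generate_matched_random(template, g, cfg)
  for (i in 1:3) expect_identical(as.data.frame(nulls[[i]]),
                                  as.data.frame(again[[i]]))
  # impossible GC target: the only GC-rich chromosome is fully covered by
  # the template, so every candidate locus is AT-only and can never match
  mixed <- Biostrings::DNAStringSet(c(chr1 = strrep("GC", 1000),
                                      chr2 = strrep("AT", 25000)))
  gc_tmpl <- peak_set("chr1", 0, 1900, score = 0)
  expect_error(
    generate_matched_random(gc_tmpl, mixed,
                            null_config(max_attempts_per_region = 50,
                                        seed = 2)),
    "attempts")
})

test_that("contains_motif scans IUPAC patterns on both strands", {
  expect_true(contains_motif("AAGGAGGGGAAA", "GGAGGGG"))
  expect_true(contains_motif("CCCCTCC", "GGAGGGG"))   # reverse complement
  expect_false(contains_motif("CCCCTCC", "GGAGGGG", both_strands = FALSE))
  expect_false(contains_motif("ACGT", "ACGTA"))       # pattern longer
  expect_false(contains_motif("TTGANNNN", "GAN", both_strands = FALSE))
  expect_true(contains_motif("TTGACT", "GAY", both_strands = FALSE))
  expect_error(contains_motif("ACGT", "AXG"), "IUPAC")
})

test_that("contains_motif agrees with the Biostrings IUPAC oracle", {
  set.seed(31)
  for (i in 1:50) {
    seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    pat <- paste(sample(c("A", "C", "G", "T", "R", "Y", "S", "W", "N"),
                        sample(3:8, 1), replace = TRUE), collapse = "")
    fwd <- Biostrings::countPattern(pat, Biostrings::DNAString(seq),
                                    fixed = "subject") > 0
    rev <- Biostrings::countPattern(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(pat))),
      Biostrings::DNAString(seq), fixed = "subject") > 0
    expect_identical(contains_motif(seq, pat, both_strands = FALSE),
                     unname(fwd))
    expect_identical(contains_motif(seq, pat, both_strands = TRUE),
                     unname(fwd || rev))
  }
})

test_that("contains_motif is reverse-complement invariant with both strands", {
  set.seed(32)
  for (i in 1:30) {
    seq <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                 collapse = "")
    pat <- paste(sample(c("A", "C", "G", "T", "R", "Y"), 6, replace = TRUE),
                 collapse = "")
    expect_identical(contains_motif(seq, pat),
                     contains_motif(reverse_complement(seq), pat))
  }
})

test_that("motif_fraction recovers planted counts", {
  tg <- tiny_genome_regions(n_regions = 4, seed = 15)
  g2 <- plant_motif(tg$genome, "GGWGGAGGTGGA", tg$regions, which = 1:3,
                    seed = 8)
  mf <- motif_fraction(tg$regions[1:4], g2, "GGWGGAGGTGGA")
  expect_equal(mf$count, 3L)
  expect_equal(mf$fraction, 0.75)
  expect_warning(
    mf0 <- motif_fraction(peak_set(character(), integer(), integer()),
                          g2, "GGWGGAGGTGGA"),
    "empty")
  expect_equal(mf0$fraction, 0)
})

test_that("enrichment_table reports the planted stratification", {
  motif <- "GGAGGAGGCGGA"
  g <- simulate_genome(c(chr1 = 40000), gc = 0.5, seed = 41)
  starts <- seq(1000, by = 3000, length.out = 8)
  obs <- peak_set(rep("chr1", 8), starts, starts + 250, score = 200)
  origins <- peak_set(rep("chr1", 4), starts[1:4] - 500, starts[1:4] - 100)
  # plant only in origin-proximal observed regions; clear everywhere else
  g2 <- plant_motif(g, motif, obs, which = 1:4, seed = 42)
  nulls <- generate_matched_random(obs, g2, null_config(seed = 43))
  tab <- enrichment_table(obs, nulls, origins, g2, motif,
                          proximity_config(cutoff_d = 2000))
  ob <- tab[tab$set == "observed", ]
  expect_equal(ob$frac_near_origin, 0.5)
  expect_equal(ob$frac_motif_near, 1.0)
  expect_equal(ob$frac_motif_far, 0.0)
  expect_equal(ob$frac_motif, 0.5)
  # null fractions reflect background, not the planted signal
  rnd <- tab[tab$set != "observed", ]
  expect_true(all(rnd$frac_motif <= 0.5))
  # nulls identical to observed reproduce the observed columns
  tab2 <- enrichment_table(obs, list(obs), origins, g2, motif,
                           proximity_config(cutoff_d = 2000))
  expect_equal(unlist(tab2[1, -1]), unlist(tab2[2, -1]))
})

test_that("null motif fraction matches the i.i.d. closed form", {
  # per-region hit probability for a fixed 12-mer on both strands of an
  # i.i.d. uniform sequence of length L: 1 - (1 - 2*4^-12)^(L-11)
  motif <- "GATCGATCGATC"
  L <- 1500; n_regions <- 60
  p_hit <- 1 - (1 - 2 * 4^-12)^(L - 11)
  hits <- 0; total <- 0
  for (sd in 1:3) {
    g <- simulate_genome(c(chr1 = 200000), gc = 0.5, seed = sd)
    starts <- seq(0, by = 3000, length.out = n_regions)
    r <- peak_set(rep("chr1", n_regions), starts, starts + L)
    hits <- hits + motif_fraction(r, g, motif)$count
    total <- total + n_regions
  }
  expect_lt(abs(hits / total - p_hit),
            3 * sqrt(p_hit * (1 - p_hit) / total) + 1e-9)
})
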