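# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth, so each analysis stage has a
# closed-loop recovery test that needs no external data.

# Quota allocation: counts per category proportional to prob, largest
# remainder rounding, then randomly permuted over n slots. Makes the
# realized mix match the requested probabilities as closely as n allows
# (exactly, when n * prob is integral).
quota_assign <- function(n, prob) {
  if (!n) return(integer(0))
  raw <- n * prob / sum(prob)
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  sample(rep.int(seq_along(prob), cnt))
}

#' Simulate a random genome
#'
#' I.i.d. bases with `P(G) + P(C) = gc` (split evenly between G and C, and
#' between A and T). Reproducible from `seed`.
#'
#' @param chrom_lengths named integer vector of chromosome lengths
#'   (>= 1000).
#' @param gc target GC fraction in (0, 1); 0 and 1 are allowed and yield
#'   all-AT / all-GC sequence.
#' @param seed integer seed.
#' @return a `DNAStringSet`.
#' @export
simulate_genome <- function(chrom_lengths = c(chr1 = 1e5), gc = 0.5,
                            seed = 1L) {
  stopifnot(gc >= 0, gc <= 1, all(chrom_lengths >= 1000))
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(chrom_lengths, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, "")
    g <- Biostrings::DNAStringSet(seqs)
    names(g) <- names(chrom_lengths)
    g
  })
}

# Realize a concrete instance of an IUPAC pattern (degenerate positions
# sampled uniformly among their allowed bases); optionally reverse strand.
realize_motif <- function(pattern, minus_strand = FALSE) {
  chars <- strsplit(.check_iupac(pattern), "")[[1L]]
  inst <- paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else sample(set, 1L)
  }, ""), collapse = "")
  if (minus_strand) reverse_complement(inst) else inst
}

#' Plant a motif into chosen regions of a genome
#'
#' Edits the genome so that exactly the chosen regions contain at least one
#' instance of the motif (planted at a random offset on a random strand),
#' and the remaining regions of `regions` contain none: any unchosen region
#' that happens to match is re-sampled base-by-base (preserving its base
#' composition) until motif-free. Ground truth for motif-containment
#' statistics.
#'
#' @param genome a `DNAStringSet`.
#' @param pattern IUPAC motif string; must fit inside every chosen region.
#' @param regions a peak-set `GRanges`.
#' @param which indices into `regions` that must carry the motif.
#' @param seed integer seed.
#' @param max_resample resampling budget per unchosen region.
#' @return the edited `DNAStringSet`.
#' @export
plant_motif <- function(genome, pattern, regions, which = seq_along(regions),
                        seed = 1L, max_resample = 1000L) {
  k <- nchar(pattern)
  if (any(GenomicRanges::width(regions)[which] < k))
    stop("motif longer than a chosen region")
  seqs <- as.character(genome)
  sub_replace <- function(chrom, at, repl) {
    substr(seqs[[chrom]], at, at + nchar(repl) - 1L) <<- repl
  }
  with_seed(seed, {
    chrom <- as.character(GenomicRanges::seqnames(regions))
    s1 <- GenomicRanges::start(regions); e1 <- GenomicRanges::end(regions)
    for (i in which) {
      off <- sample.int(e1[i] - s1[i] + 1L - k + 1L, 1L)
      inst <- realize_motif(pattern, minus_strand = runif(1) < 0.5)
      sub_replace(chrom[i], s1[i] + off - 1L, inst)
    }
    for (i in setdiff(seq_along(regions), which)) {
      for (att in seq_len(max_resample)) {
        cur <- substr(seqs[[chrom[i]]], s1[i], e1[i])
        if (!contains_motif(cur, pattern)) break
        bases <- strsplit(cur, "")[[1L]]
        sub_replace(chrom[i], s1[i], paste(sample(bases), collapse = ""))
        if (att == max_resample)
          stop("could not clear motif from region ", i)
      }
    }
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(genome)
  out
}

#' Simulate an anchor/event peak pair with known colocalization fraction
#'
#' Places `round(colocal_fraction * n_anchors)` anchors with one event at an
#' edge-to-edge gap drawn uniformly from `[0, cutoff_d]`, and the remaining
#' anchors at least `5 * cutoff_d` away from every event, so the ground
#' truth is unambiguous under both gap and centre distance rules. Any
#' events beyond those paired with anchors are placed in isolation.
#' Placement uses fixed-stride slots jittered at most `jitter` bp,
#' partitioned over chromosomes by capacity.
#'
#' @param n_anchors,n_events set sizes; `n_events >=` number of colocalized
#'   anchors.
#' @param colocal_fraction target fraction of colocalized anchors in
#'   `[0, 1]`.
#' @param cutoff_d proximity cutoff the ground truth refers to (bp).
#' @param genome_lengths named vector of chromosome lengths.
#' @param anchor_len,event_len length ranges `c(min, max)` bp; event
#'   default 500-1000 bp mimics nascent-strand peak sizes.
#' @param score_range anchor score range `c(min, max)`.
#' @param jitter per-slot placement jitter (bp).
#' @param seed integer seed.
#' @return list with `anchors` and `events` peak-set `GRanges`;
#'   `attr(, "n_colocal")` records the planted count.
#' @export
simulate_peak_pair <- function(n_anchors = 1000L, n_events = n_anchors,
                               colocal_fraction = 0.8, cutoff_d = 2000L,
                               genome_lengths = c(chr1 = 3e7, chr2 = 3e7),
                               anchor_len = c(200L, 1000L),
                               event_len = c(500L, 1000L),
                               score_range = c(0, 1000),
                               jitter = 1000L, seed = 1L) {
  stopifnot(colocal_fraction >= 0, colocal_fraction <= 1)
  n_coloc <- as.integer(round(colocal_fraction * n_anchors))
  if (n_events < n_coloc)
    stop("n_events must be at least the number of colocalized anchors")
  n_lone_anchor <- n_anchors - n_coloc
  n_lone_event <- n_events - n_coloc
  n_slots <- n_coloc + n_lone_anchor + n_lone_event
  stride <- 5L * cutoff_d + anchor_len[2L] + cutoff_d + event_len[2L] +
    jitter + 1000L
  cap <- floor(genome_lengths / stride)
  if (sum(cap) < n_slots)
    stop("genome too small: need ", n_slots, " slots of ", stride,
         " bp, capacity ", sum(cap))
  with_seed(seed, {
    # assign slots to chromosomes, then slot roles at random
    chrom_of <- rep(names(genome_lengths), pmin(cap, n_slots))[seq_len(n_slots)]
    slot_in_chrom <- unlist(lapply(table(factor(chrom_of,
                                                names(genome_lengths))),
                                   seq_len), use.names = FALSE)
    role <- sample(rep.int(c("coloc", "anchor", "event"),
                           c(n_coloc, n_lone_anchor, n_lone_event)))
    base <- (slot_in_chrom - 1L) * stride +
      floor(runif(n_slots, 0, jitter + 1))
    a_chr <- character(0); a_s <- a_e <- numeric(0)
    e_chr <- character(0); e_s <- e_e <- numeric(0)
    for (i in seq_len(n_slots)) {
      la <- floor(runif(1, anchor_len[1L], anchor_len[2L] + 1))
      le <- floor(runif(1, event_len[1L], event_len[2L] + 1))
      if (role[i] == "coloc") {
        g <- floor(runif(1, 0, cutoff_d + 1))
        a_chr <- c(a_chr, chrom_of[i]); a_s <- c(a_s, base[i])
        a_e <- c(a_e, base[i] + la)
        e_chr <- c(e_chr, chrom_of[i]); e_s <- c(e_s, base[i] + la + g)
        e_e <- c(e_e, base[i] + la + g + le)
      } else if (role[i] == "anchor") {
        a_chr <- c(a_chr, chrom_of[i]); a_s <- c(a_s, base[i])
        a_e <- c(a_e, base[i] + la)
      } else {
        e_chr <- c(e_chr, chrom_of[i]); e_s <- c(e_s, base[i])
        e_e <- c(e_e, base[i] + le)
      }
    }
    anchors <- peak_set(a_chr, a_s, a_e,
                        name = paste0("anchor_", seq_along(a_s)),
                        score = round(runif(length(a_s), score_range[1L],
                                            score_range[2L])),
                        label = "synthetic_anchors")
    events <- peak_set(e_chr, e_s, e_e,
                       name = paste0("event_", seq_along(e_s)),
                       score = 0, label = "synthetic_events")
    out <- list(anchors = anchors, events = events)
    attr(out, "n_colocal") <- n_coloc
    out
  })
}

#' Fibre-population simulation parameters
#'
#' Defaults describe a wild-type-like population: gamma-distributed
#' inter-origin spacing with median 102.6 kb (shape 4, reflecting
#' under-dispersed origin spacing relative to a Poisson process), fork
#' speeds normal with mean 1.570 kb/min and sd 0.3 truncated positive, two
#' 30-min pulses at 2 kb/um, and no stalling. Stalling multiplies a fork
#' side's second-pulse track by `stall_factor` with probability
#' `stall_prob` per side (quota-allocated over sides so the realized mix is
#' exact; see package vignette).
#'
#' @param n_fibers number of fibres.
#' @param origins_per_fiber mean extra origins per labelled fibre; each
#'   labelled fibre carries `1 + Poisson(origins_per_fiber)` origins.
#' @param spacing_median_kb target median consecutive-origin spacing.
#' @param spacing_shape gamma shape (`Inf` is not allowed; use large for
#'   near-constant spacing, 1 for exponential).
#' @param speed_mean,speed_sd fork-speed distribution (kb/min), truncated
#'   at > 0.
#' @param stall_prob per-fork-side stalling probability.
#' @param stall_factor multiplicative shortening of a stalled side's
#'   second-pulse track.
#' @param signal_fraction fraction of fibres carrying replication signal
#'   (quota-allocated). Default 1: every fibre is labelled, the natural
#'   setting for recovery tests; lower it to emulate sparse labelling.
#' @param unlabeled_length_kb length range of signal-free fibres.
#' @param margin_kb range of unreplicated fibre ends flanking the origin
#'   cluster.
#' @param pulse_minutes,scale_kb_per_um labelling and stretching constants.
#' @param seed integer seed.
#' @return a `fiber_sim_spec` list.
#' @export
fiber_sim_spec <- function(n_fibers = 1000L, origins_per_fiber = 2,
                           spacing_median_kb = 102.6, spacing_shape = 4,
                           speed_mean = 1.570, speed_sd = 0.3,
                           stall_prob = 0, stall_factor = 0.5,
                           signal_fraction = 1.0,
                           unlabeled_length_kb = c(150, 500),
                           margin_kb = c(20, 60),
                           pulse_minutes = 30, scale_kb_per_um = 2,
                           seed = 1L) {
  stopifnot(n_fibers >= 1, spacing_median_kb > 0, spacing_shape > 0,
            speed_mean > 0, speed_sd >= 0,
            stall_prob >= 0, stall_prob <= 1,
            stall_factor > 0, stall_factor < 1,
            signal_fraction >= 0, signal_fraction <= 1)
  structure(list(n_fibers = as.integer(n_fibers),
                 origins_per_fiber = origins_per_fiber,
                 spacing_median_kb = spacing_median_kb,
                 spacing_shape = spacing_shape,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 stall_prob = stall_prob, stall_factor = stall_factor,
                 signal_fraction = signal_fraction,
                 unlabeled_length_kb = unlabeled_length_kb,
                 margin_kb = margin_kb,
                 pulse_minutes = pulse_minutes,
                 scale_kb_per_um = scale_kb_per_um,
                 seed = as.integer(seed)),
            class = "fiber_sim_spec")
}

# gamma scale such that the distribution's median equals target
.gamma_scale_for_median <- function(median_kb, shape) {
  median_kb / stats::qgamma(0.5, shape = shape, scale = 1)
}

#' Simulate a combed-fibre segment table
#'
#' Generates the fibre dialect consumed by [read_fiber_table()] /
#' [summarize_conditions()]. Each labelled fibre carries
#' `1 + Poisson(origins_per_fiber)` origins separated by gamma-distributed
#' spacings; every origin fires at the start of the first pulse and emits
#' two forks whose speeds are drawn independently (truncated normal). The
#' first pulse produces one central initiating (IdU) segment spanning both
#' forks' first-pulse tracks; the second pulse produces the two flanking
#' CldU segments. Facing forks of adjacent origins terminate where they
#' meet (their joint track cannot exceed the drawn spacing); a fork that
#' terminates before the end of the second pulse has its CldU segment
#' marked `terminating`, which downstream speed statistics exclude —
#' mirroring the practice of measuring elongating forks only. A stalled
#' side's second-pulse track is shortened multiplicatively by
#' `stall_factor`. Segment lengths are emitted in micrometres (kb divided
#' by `scale_kb_per_um`), with `gap` rows for unreplicated stretches so
#' that positions along the fibre reconstruct by cumulative sums.
#'
#' @param spec a [fiber_sim_spec()].
#' @param condition condition label stamped on every row.
#' @return a fibre segment data.frame (see [read_fiber_table()]), with
#'   attribute `truth`: realized spacings, speeds, stall and termination
#'   flags.
#' @export
simulate_fibers <- function(spec = fiber_sim_spec(), condition = "WT") {
  scale <- .gamma_scale_for_median(spec$spacing_median_kb,
                                   spec$spacing_shape)
  pulse <- spec$pulse_minutes
  total_t <- 2 * pulse
  kb2um <- function(kb) kb / spec$scale_kb_per_um
  with_seed(spec$seed, {
    labeled <- quota_assign(spec$n_fibers,
                            c(spec$signal_fraction,
                              1 - spec$signal_fraction)) == 1L
    n_orig_per <- ifelse(labeled, 1L + rpois(spec$n_fibers,
                                             spec$origins_per_fiber), 0L)
    total_origins <- sum(n_orig_per)
    # quota-allocate stall outcomes over origins: (none, left, right, both)
    p <- spec$stall_prob
    outcome <- quota_assign(total_origins,
                            c((1 - p)^2, p * (1 - p), p * (1 - p), p^2))
    rows <- vector("list", spec$n_fibers)
    truth <- list(spacings = numeric(0), speeds = numeric(0),
                  stalled = logical(0), terminated = logical(0))
    oi <- 0L
    rspeed <- function(n) {
      v <- rnorm(n, spec$speed_mean, spec$speed_sd)
      while (any(v <= 0)) v[v <= 0] <- rnorm(sum(v <= 0), spec$speed_mean,
                                             spec$speed_sd)
      v
    }
    for (f in seq_len(spec$n_fibers)) {
      fid <- sprintf("%s_fiber_%05d", condition, f)
      if (!labeled[f]) {
        L <- runif(1, spec$unlabeled_length_kb[1L],
                   spec$unlabeled_length_kb[2L])
        rows[[f]] <- data.frame(
          fiber_id = fid, condition = condition, segment_index = 1L,
          label = "none", kind = "none", length_um = kb2um(L),
          origin_id = NA_character_, side = NA_character_,
          ssdna_length_um = kb2um(L), stringsAsFactors = FALSE)
        next
      }
      k <- n_orig_per[f]
      spac <- if (k > 1) rgamma(k - 1L, shape = spec$spacing_shape,
                                scale = scale) else numeric(0)
      centers <- cumsum(c(0, spac))
      vl <- rspeed(k); vr <- rspeed(k)
      out_f <- outcome[oi + seq_len(k)]; oi <- oi + k
      stall_l <- out_f %in% c(2L, 4L); stall_r <- out_f %in% c(3L, 4L)
      # running time per side: outer forks run the full two pulses, facing
      # forks of adjacent origins stop where they meet
      t_l <- rep(total_t, k); t_r <- rep(total_t, k)
      if (k > 1) for (j in seq_len(k - 1L)) {
        t_meet <- spac[j] / (vr[j] + vl[j + 1L])
        t_r[j] <- min(t_r[j], t_meet)
        t_l[j + 1L] <- min(t_l[j + 1L], t_meet)
      }
      idu_l <- vl * pmin(t_l, pulse); idu_r <- vr * pmin(t_r, pulse)
      cldu_l <- vl * (t_l - pmin(t_l, pulse)) *
        ifelse(stall_l, spec$stall_factor, 1)
      cldu_r <- vr * (t_r - pmin(t_r, pulse)) *
        ifelse(stall_r, spec$stall_factor, 1)
      term_l <- t_l < total_t; term_r <- t_r < total_t
      left_ext <- idu_l + vl * (t_l - pmin(t_l, pulse))  # unstalled extent
      right_ext <- idu_r + vr * (t_r - pmin(t_r, pulse))
      m0 <- runif(1, spec$margin_kb[1L], spec$margin_kb[2L])
      centers <- centers + m0 + left_ext[1L]
      m1 <- runif(1, spec$margin_kb[1L], spec$margin_kb[2L])
      fiber_len <- centers[k] + right_ext[k] + m1
      # ordered segments: gap | CldU_left | IdU | CldU_right | gap | ...
      seg <- list(); si <- 0L
      push <- function(label, kind, len_kb, orig = NA_character_,
                       side = NA_character_) {
        si <<- si + 1L
        seg[[si]] <<- data.frame(
          fiber_id = fid, condition = condition, segment_index = si,
          label = label, kind = kind, length_um = kb2um(len_kb),
          origin_id = orig, side = side,
          ssdna_length_um = kb2um(fiber_len), stringsAsFactors = FALSE)
      }
      pos <- 0
      for (j in seq_len(k)) {
        oid <- sprintf("%s_ori_%d", fid, j)
        gap_len <- (centers[j] - idu_l[j] - cldu_l[j]) - pos
        if (gap_len > 1e-9) push("none", "gap", gap_len)
        if (cldu_l[j] > 0)
          push("CldU", if (term_l[j]) "terminating" else "elongating",
               cldu_l[j], oid, "left")
        push("IdU", "initiating", idu_l[j], oid, "left")
        push("IdU", "initiating", idu_r[j], oid, "right")
        if (cldu_r[j] > 0)
          push("CldU", if (term_r[j]) "terminating" else "elongating",
               cldu_r[j], oid, "right")
        pos <- centers[j] + idu_r[j] + cldu_r[j]
      }
      if (fiber_len - pos > 1e-9) push("none", "gap", fiber_len - pos)
      rows[[f]] <- do.call(rbind, seg)
      truth$spacings <- c(truth$spacings, spac)
      truth$speeds <- c(truth$speeds, vl, vr)
      truth$stalled <- c(truth$stalled, stall_l, stall_r)
      truth$terminated <- c(truth$terminated, term_l, term_r)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    out
  })
}

#' Write a fibre segment table to delimited text
#' @param tab fibre segment data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fiber_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
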