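#' DNA-combing measurement configuration
#'
#' Conversion and classification constants for fibre analysis. Stretched
#' DNA is converted from micrometres to kilobases with a constant factor
#' (default 2 kb/um, the standard combing stretch calibration); fork speed
#' divides the second-pulse track length by the pulse duration (default
#' 30 min); a fork pair is called asymmetric when one side is more than
#' `asymmetry_threshold` (default 33%) longer than the other.
#'
#' @param scale_kb_per_um kb per micrometre of combed fibre (default 2).
#' @param pulse_minutes duration of each labelling pulse (default 30).
#' @param asymmetry_threshold relative excess length calling a fork pair
#'   asymmetric; strict inequality `max/min > 1 + threshold` (default 0.33).
#' @param speed_label which label's elongating tracks measure speed:
#'   `"CldU"` (second pulse, default), `"IdU"`, or `"both"`.
#' @return a `fiber_config` list.
#' @export
fiber_config <- function(scale_kb_per_um = 2.0, pulse_minutes = 30,
                         asymmetry_threshold = 0.33,
                         speed_label = c("CldU", "IdU", "both")) {
  speed_label <- match.arg(speed_label)
  stopifnot(scale_kb_per_um > 0, pulse_minutes > 0,
            asymmetry_threshold > 0, asymmetry_threshold <= 1)
  structure(list(scale_kb_per_um = scale_kb_per_um,
                 pulse_minutes = pulse_minutes,
                 asymmetry_threshold = asymmetry_threshold,
                 speed_label = speed_label),
            class = "fiber_config")
}

#' Convert combed-fibre micrometres to kilobases
#' @param length_um measured length(s) in micrometres (>= 0).
#' @param cfg a [fiber_config()].
#' @return lengths in kb.
#' @export
um_to_kb <- function(length_um, cfg = fiber_config()) {
  if (any(length_um < 0)) stop("negative length")
  length_um * cfg$scale_kb_per_um
}

#' Fork speed from an elongating track
#'
#' `um_to_kb(track_um) / pulse_minutes`. Callers must pass elongating-fork
#' tracks only; initiation tracks (which accumulate label from two forks)
#' overestimate speed and are excluded upstream.
#'
#' @param track_um elongating-track length(s) in micrometres.
#' @param cfg a [fiber_config()].
#' @return speed in kb/min. `fork_speed(23.55)` is 1.570 at defaults.
#' @export
fork_speed <- function(track_um, cfg = fiber_config()) {
  um_to_kb(track_um, cfg) / cfg$pulse_minutes
}

#' Classify a fork pair as symmetric or asymmetric
#'
#' A bidirectional origin emits a left and a right fork; the pair is
#' asymmetric when the longer side exceeds the shorter by strictly more
#' than the threshold (default: ratio > 1.33). One side of length zero
#' with the other positive is asymmetric; both zero is an error.
#' Vectorized; symmetric in its two arguments.
#'
#' @param left_kb,right_kb outgoing track lengths in kb (>= 0).
#' @param cfg a [fiber_config()].
#' @return character vector, `"symmetric"` or `"asymmetric"`.
#' @examples
#' classify_fork(13.4, 10)  # asymmetric (ratio 1.34)
#' classify_fork(13.3, 10)  # symmetric (ratio exactly 1.33, strict rule)
#' @export
classify_fork <- function(left_kb, right_kb, cfg = fiber_config()) {
  if (any(left_kb < 0 | right_kb < 0)) stop("negative track length")
  if (any(left_kb == 0 & right_kb == 0))
    stop("fork pair with both sides zero")
  hi <- pmax(left_kb, right_kb); lo <- pmin(left_kb, right_kb)
  ifelse(lo == 0 | hi / lo > 1 + cfg$asymmetry_threshold,
         "asymmetric", "symmetric")
}

#' Read a fibre segment table
#'
#' One row per measured label segment, ordered along each fibre. Required
#' columns: `fiber_id`, `condition`, `segment_index`, `label` (one of
#' `IdU`, `CldU`, `none`), `length_um` (> 0; unlabelled `none` rows may be
#' 0), `kind` (one of `elongating`, `initiating`, `terminating`,
#' `unclassified`, `gap`, `none`). Optional: `origin_id` and `side`
#' (`left`/`right`) linking second-pulse tracks into fork pairs, and
#' `ssdna_length_um` (total counter-stained fibre length). Fibres without
#' any replication signal are recorded as a single `label = "none"` row.
#'
#' @param path delimited text file (tab-separated).
#' @return validated data.frame.
#' @export
read_fiber_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("fiber_id", "condition", "segment_index", "label",
           "length_um", "kind")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("fiber table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(tab$label %in% c("IdU", "CldU", "none")))
    stop("label must be IdU, CldU or none")
  kinds <- c("elongating", "initiating", "terminating", "unclassified",
             "gap", "none")
  if (!all(tab$kind %in% kinds))
    stop("kind must be one of: ", paste(kinds, collapse = ", "))
  if (any(tab$length_um < 0) ||
      any(tab$length_um == 0 & tab$label != "none"))
    stop("labelled segment lengths must be > 0")
  tab[order(tab$fiber_id, tab$segment_index), , drop = FALSE]
}

#' Inter-origin distances on one fibre
#'
#' Origin positions are located on initiation-pattern (`kind ==
#' "initiating"`) segments, positioned by cumulative segment length along
#' the fibre; distances between consecutive origin centres are returned in
#' kb. When an origin's initiating tract is recorded as sided left/right
#' rows, the origin centre is the junction between them (the point from
#' which the two forks diverged); otherwise it is the midpoint of the
#' origin's initiating span. Fibres with fewer than two origins yield an
#' empty vector.
#'
#' @param fiber_segments data.frame of one fibre's rows (see
#'   [read_fiber_table()]); all segments including `gap` rows must be
#'   present for positions to be meaningful.
#' @param cfg a [fiber_config()].
#' @return numeric vector of consecutive inter-origin distances (kb).
#' @export
inter_origin_distances <- function(fiber_segments, cfg = fiber_config()) {
  seg <- fiber_segments[order(fiber_segments$segment_index), , drop = FALSE]
  ends_um <- cumsum(seg$length_um)
  starts_um <- ends_um - seg$length_um
  init <- which(seg$kind == "initiating")
  if (!length(init)) return(numeric(0))
  grp <- if (!is.null(seg$origin_id) && !anyNA(seg$origin_id[init]))
    seg$origin_id[init] else as.character(init)
  side <- if (!is.null(seg$side)) seg$side[init] else rep(NA, length(init))
  centers_um <- vapply(split(seq_along(init), grp), function(ix) {
    lft <- ix[!is.na(side[ix]) & side[ix] == "left"]
    if (length(lft)) max(ends_um[init[lft]])           # fork divergence point
    else (min(starts_um[init[ix]]) + max(ends_um[init[ix]])) / 2
  }, 0)
  centers_um <- sort(unname(centers_um))
  if (length(centers_um) < 2L) return(numeric(0))
  diff(um_to_kb(centers_um, cfg))
}

#' Two-sample Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided test of identical distributions. For small groups (both sizes
#' `<= exact_limit`) the null distribution of U is enumerated exactly over
#' all assignments of the pooled observations, which remains valid under
#' ties; otherwise the normal approximation with tie-corrected variance
#' (and optional continuity correction) is used.
#'
#' @param x,y numeric samples.
#' @param exact_limit use exact enumeration when both groups are at most
#'   this large (default 8).
#' @param continuity apply continuity correction in the approximation.
#' @return a list with `statistic` (U for `x`), `p_value` and `method`.
#' @export
mw_test <- function(x, y, exact_limit = 8L, continuity = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_limit && n2 <= exact_limit) {
    # enumerate U over all choose(n1+n2, n1) group assignments
    idx <- combn(n1 + n2, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- mean(abs(us - mu) >= abs(u - mu) - eps)
    return(list(statistic = u, p_value = p, method = "exact"))
  }
  n <- n1 + n2
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p_value = 1,
                               method = "normal"))
  z <- u - mu
  if (continuity) z <- sign(z) * max(abs(z) - 0.5, 0)
  p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
  list(statistic = u, p_value = p, method = "normal")
}

# Per-fiber fork pairs: second-pulse (or cfg$speed_label) elongating tracks
# joined by origin_id/side into (left, right) kb pairs.
fiber_fork_pairs <- function(tab, cfg = fiber_config()) {
  if (is.null(tab$origin_id) || is.null(tab$side))
    return(data.frame(fiber_id = character(), condition = character(),
                      origin_id = character(), left_kb = numeric(),
                      right_kb = numeric()))
  sel <- tab$label == "CldU" & tab$kind == "elongating" &
    !is.na(tab$origin_id) & tab$side %in% c("left", "right")
  seg <- tab[sel, , drop = FALSE]
  if (!nrow(seg))
    return(data.frame(fiber_id = character(), condition = character(),
                      origin_id = character(), left_kb = numeric(),
                      right_kb = numeric()))
  key <- paste(seg$fiber_id, seg$origin_id, sep = "\r")
  lk <- tapply(ifelse(seg$side == "left", seg$length_um, NA), key,
               function(v) v[!is.na(v)][1])
  rk <- tapply(ifelse(seg$side == "right", seg$length_um, NA), key,
               function(v) v[!is.na(v)][1])
  info <- seg[!duplicated(key), c("fiber_id", "condition", "origin_id")]
  keys <- key[!duplicated(key)]
  out <- data.frame(info,
                    left_kb = unname(lk[keys]) * cfg$scale_kb_per_um,
                    right_kb = unname(rk[keys]) * cfg$scale_kb_per_um,
                    stringsAsFactors = FALSE)
  out[!is.na(out$left_kb) & !is.na(out$right_kb), , drop = FALSE]
}

#' Summarize fibre replication statistics per condition
#'
#' Computes, for each condition in the table: the median inter-origin
#' distance (kb) over all fibres; the median fork speed (kb/min) from
#' elongating tracks of the configured label; the percentage of fork pairs
#' classified asymmetric; and the percentage of fibres exhibiting any
#' replication signal (at least one IdU/CldU segment; the denominator is
#' all fibres present in the table). When `condition_a` and `condition_b`
#' are given, two-sided Mann-Whitney rank-sum p-values compare their
#' inter-origin distances and fork speeds. Medians are computed on the raw
#' unbinned measurement lists.
#'
#' @param tab fibre segment table (see [read_fiber_table()]).
#' @param cfg a [fiber_config()].
#' @param condition_a,condition_b condition labels to compare (optional;
#'   must exist in the table when given).
#' @return a `fiber_summary` list: `per_condition` data.frame and
#'   `p_distance`, `p_speed` (NA when no comparison requested or fewer than
#'   3 observations per group).
#' @export
summarize_conditions <- function(tab, cfg = fiber_config(),
                                 condition_a = NULL, condition_b = NULL) {
  conds <- unique(tab$condition)
  for (cc in c(condition_a, condition_b))
    if (!is.null(cc) && !cc %in% conds)
      stop("unknown condition label: ", cc)
  speed_lab <- if (cfg$speed_label == "both") c("IdU", "CldU")
               else cfg$speed_label
  per <- lapply(conds, function(cc) {
    sub <- tab[tab$condition == cc, , drop = FALSE]
    dists <- unlist(lapply(split(sub, sub$fiber_id),
                           inter_origin_distances, cfg = cfg),
                    use.names = FALSE)
    sp_seg <- sub[sub$label %in% speed_lab & sub$kind == "elongating", ,
                  drop = FALSE]
    speeds <- fork_speed(sp_seg$length_um, cfg)
    pairs <- fiber_fork_pairs(sub, cfg)
    cls <- if (nrow(pairs)) classify_fork(pairs$left_kb, pairs$right_kb, cfg)
           else character(0)
    has_sig <- tapply(sub$label %in% c("IdU", "CldU"), sub$fiber_id, any)
    list(condition = cc,
         distances = dists, speeds = speeds,
         row = data.frame(
           condition = cc,
           n_fibers = length(has_sig),
           n_fibers_signal = sum(has_sig),
           pct_fibers_signal = 100 * mean(has_sig),
           n_distances = length(dists),
           median_interorigin_kb = if (length(dists)) median(dists) else NA,
           n_forks = length(speeds),
           median_speed_kb_min = if (length(speeds)) median(speeds) else NA,
           n_fork_pairs = length(cls),
           pct_asymmetric = if (length(cls)) 100 * mean(cls == "asymmetric")
                            else NA,
           stringsAsFactors = FALSE))
  })
  names(per) <- conds
  p_dist <- p_speed <- NA_real_
  if (!is.null(condition_a) && !is.null(condition_b)) {
    da <- per[[condition_a]]$distances; db <- per[[condition_b]]$distances
    sa <- per[[condition_a]]$speeds; sb <- per[[condition_b]]$speeds
    if (length(da) >= 3 && length(db) >= 3)
      p_dist <- mw_test(da, db)$p_value
    if (length(sa) >= 3 && length(sb) >= 3)
      p_speed <- mw_test(sa, sb)$p_value
  }
  structure(list(
    per_condition = do.call(rbind, lapply(per, `[[`, "row")),
    p_distance = p_dist, p_speed = p_speed,
    condition_a = condition_a, condition_b = condition_b
  ), class = "fiber_summary")
}

#' @export
print.fiber_summary <- function(x, ...) {
  print(x$per_condition, row.names = FALSE)
  if (!is.na(x$p_distance) || !is.na(x$p_speed))
    cat(sprintf("Mann-Whitney (%s vs %s): inter-origin p = %.4g, speed p = %.4g\n",
                x$condition_a, x$condition_b, x$p_distance, x$p_speed))
  invisible(x)
}
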