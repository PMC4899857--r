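# Pipeline orchestration and the command-line surface. Every number the
# combined report emits is reproducible by calling the corresponding
# single-stage function (or CLI subcommand) with the parameters recorded in
# the run manifest.

#' Assemble a pipeline configuration
#'
#' Plain list of input paths and stage parameters. Stages run only when
#' their inputs are present: colocalization/profile/stratification need
#' `anchors` + `events`; subset selection needs `anchors`; the randomized
#' null and motif enrichment need `genome` + `motif` (and `events` as the
#' origin set); fibre statistics need `fiber_table`; the coexpression
#' screen needs `expression` + `candidates` + `replication_genes`.
#' Validation errors are raised before any computation.
#'
#' @param anchors,events,genome,fiber_table,expression input file paths
#'   (BED, BED, FASTA, TSV, TSV); any may be `NULL`.
#' @param motif IUPAC motif string, or `NULL`.
#' @param candidates,replication_genes character vectors of gene names for
#'   the coexpression screen.
#' @param fiber_conditions length-2 character vector of condition labels to
#'   compare, or `NULL`.
#' @param out_dir output directory (created).
#' @param proximity a [proximity_config()].
#' @param subset a [subset_criteria()].
#' @param null_cfg a [null_config()]; its seed is overridden by `seed`.
#' @param fiber_cfg a [fiber_config()].
#' @param seed master seed; per-stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(anchors = NULL, events = NULL, genome = NULL,
                            motif = NULL, fiber_table = NULL,
                            expression = NULL, candidates = NULL,
                            replication_genes = NULL,
                            fiber_conditions = NULL,
                            out_dir = "oritools_out",
                            proximity = proximity_config(),
                            subset = subset_criteria(),
                            null_cfg = null_config(),
                            fiber_cfg = fiber_config(),
                            seed = 1L) {
  cfg <- list(anchors = anchors, events = events, genome = genome,
              motif = motif, fiber_table = fiber_table,
              expression = expression, candidates = candidates,
              replication_genes = replication_genes,
              fiber_conditions = fiber_conditions,
              out_dir = out_dir, proximity = proximity, subset = subset,
              null_cfg = null_cfg, fiber_cfg = fiber_cfg,
              seed = as.integer(seed))
  for (f in c("anchors", "events", "genome", "fiber_table", "expression"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config error: ", f, " file does not exist: ", cfg[[f]])
  if (!is.null(motif)) {
    .check_iupac(motif)
    if (is.null(genome))
      stop("config error: motif enrichment requested but no genome given")
    if (is.null(anchors))
      stop("config error: motif enrichment requested but no anchors given")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order and as inputs allow: colocalization summary, distance
#' profile, origin stratification, peak-subset selection, GC-matched
#' randomization, motif enrichment, fibre statistics, coexpression ranking.
#' Each stage writes its table/BED under `out_dir`; a JSON manifest records
#' every parameter, derived seed, input checksum, package version and
#' per-stage wall time. A stage failure aborts with the stage name and
#' leaves a `FAILED` marker file; earlier outputs are retained.
#'
#' @param cfg a [pipeline_config()].
#' @return named list of stage results (also written to disk), invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "oritools",
    version = as.character(utils::packageVersion("oritools")),
    seed = cfg$seed,
    parameters = list(proximity = unclass(cfg$proximity),
                      subset = unclass(cfg$subset),
                      null_cfg = unclass(cfg$null_cfg),
                      fiber_cfg = unclass(cfg$fiber_cfg),
                      motif = cfg$motif),
    inputs = list(), stages = list()
  )
  for (f in c("anchors", "events", "genome", "fiber_table", "expression"))
    if (!is.null(cfg[[f]]))
      manifest$inputs[[f]] <- list(path = cfg[[f]],
                                   md5 = unname(tools::md5sum(cfg[[f]])))
  results <- list()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    results[[name]] <<- res
    res
  }
  out <- function(f) file.path(cfg$out_dir, f)

  anchors <- if (!is.null(cfg$anchors)) read_bed(cfg$anchors)
  events <- if (!is.null(cfg$events)) read_bed(cfg$events)
  genome <- if (!is.null(cfg$genome)) read_genome(cfg$genome)

  if (!is.null(anchors) && !is.null(events)) {
    stage("colocalize", function() {
      s <- fraction_within(anchors, events, cfg$proximity)
      df <- as.data.frame(unclass(s)[c("n_anchors", "n_anchors_colocal",
                                       "fraction", "n_events",
                                       "n_events_colocal",
                                       "fraction_reverse", "cutoff_d")])
      write.table(df, out("colocalization.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      s
    })
    stage("profile", function() {
      p <- distance_profile(anchors, events, cfg$proximity)
      write.table(p, out("distance_profile.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      p
    })
    stage("stratify", function() {
      st <- stratify_origins(events, anchors, cfg$proximity)
      write_bed(st$bound, out("origins.bound.bed"))
      write_bed(st$unbound, out("origins.unbound.bed"))
      st
    })
  }
  if (!is.null(anchors)) {
    stage("select_peaks", function() {
      sel <- select_peak_subset(anchors, cfg$subset)
      write_bed(sel, out("selected_subset.bed"))
      if (!is.null(genome))
        write_genome(region_sequences(genome, sel),
                     out("selected_subset.fa"))
      sel
    })
  }
  if (!is.null(cfg$motif)) {
    stage("randomize", function() {
      ncfg <- cfg$null_cfg
      ncfg$seed <- cfg$seed + 1000L  # stage-derived seed
      nulls <- generate_matched_random(results$select_peaks, genome, ncfg)
      for (i in seq_along(nulls))
        write_bed(nulls[[i]], out(sprintf("random_%d.bed", i)))
      nulls
    })
    stage("motif_enrich", function() {
      tab <- enrichment_table(results$select_peaks, results$randomize,
                              events %||% peak_set(character(), integer(),
                                                   integer()),
                              genome, cfg$motif, cfg$proximity)
      write.table(tab, out("motif_enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      tab
    })
  }
  if (!is.null(cfg$fiber_table)) {
    stage("fibers", function() {
      tab <- read_fiber_table(cfg$fiber_table)
      fc <- cfg$fiber_conditions
      s <- summarize_conditions(tab, cfg$fiber_cfg,
                                condition_a = fc[1] %||% NULL,
                                condition_b = if (length(fc) > 1) fc[2])
      write.table(s$per_condition, out("fiber_summary.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      s
    })
  }
  if (!is.null(cfg$expression)) {
    stage("coexpress", function() {
      if (is.null(cfg$candidates) || is.null(cfg$replication_genes))
        stop("coexpression requested without candidates/replication genes")
      m <- read_expression_matrix(cfg$expression)
      r <- coexpression_rank(m, cfg$candidates, cfg$replication_genes)
      write.table(r, out("coexpression_rank.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      r
    })
  }
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(results)
}
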