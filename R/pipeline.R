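#' Configuration of an end-to-end database-growth run
#'
#' Bundles every choice of the analysis — input database (synthetic
#' configuration, or FASTA paths with a header dialect), which filters to
#' apply, the subsampling grid, the identity thresholds, and the replicate
#' aggregation mode — into one serializable object.  A snapshot of the
#' configuration is written into each run directory, and a run is fully
#' reproducible from config plus seed.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading FASTA.
#' @param fasta_paths,dialect FASTA input (ignored when `synthetic` given).
#' @param filters Character subset of `c("taxonomy", "length")`.
#' @param sizes,n_replicates,nested Subsampling grid, see
#'   [subsample_spec()].
#' @param thresholds Identity thresholds to cluster at.
#' @param aggregate Replicate aggregation (`"median"` or `"mean"`).
#' @param seed Master seed; the synthetic generator and every subset derive
#'   their own seeds from it.
#' @param write_fasta Also write the filtered database as FASTA.
#' @param write_clusterings Also write every clustering (`.clstr` + TSV);
#'   off by default since a full grid produces many files.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, fasta_paths = NULL,
                       dialect = "silva",
                       filters = c("taxonomy", "length"),
                       sizes, n_replicates = 1L, nested = FALSE,
                       thresholds = c(0.95, 0.97, 0.99, 1.0),
                       aggregate = c("median", "mean"),
                       seed = 1L,
                       write_fasta = FALSE, write_clusterings = FALSE) {
  aggregate <- match.arg(aggregate)
  if (is.null(synthetic) && is.null(fasta_paths))
    stop("configuration error: either synthetic config or FASTA paths")
  stopifnot(all(filters %in% c("taxonomy", "length")),
            all(thresholds > 0), all(thresholds <= 1))
  structure(list(synthetic = synthetic, fasta_paths = fasta_paths,
                 dialect = dialect, filters = filters,
                 sizes = as.integer(sizes),
                 n_replicates = as.integer(n_replicates),
                 nested = isTRUE(nested), thresholds = thresholds,
                 aggregate = aggregate, seed = as.integer(seed),
                 write_fasta = isTRUE(write_fasta),
                 write_clusterings = isTRUE(write_clusterings)),
            class = "run_config")
}

config_snapshot <- function(config) {
  x <- unclass(config)
  if (!is.null(x$synthetic)) {
    x$synthetic <- lapply(unclass(x$synthetic), function(v)
      if (is.function(v)) paste(deparse(v), collapse = " ") else v)
  }
  x
}

#' Run the full database-growth collision analysis
#'
#' Executes the workflow end to end: obtain the database (generate
#' synthetically or read FASTA), apply the taxonomy and length filters,
#' draw the simulated databases over the size grid with replication,
#' cluster each simulated database at each identity threshold, compute
#' multi-species-cluster statistics, species-pair co-occurrences, the
#' genus-richness relation (on the largest size, first replicate), and the
#' power-law growth-rate fits; write every table as TSV into `outdir`
#' together with a config snapshot and a stage log.  Re-running with the
#' same config and seed reproduces all tables byte-identically; subsets are
#' independent work units whose evaluation order cannot affect any output.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created; must be empty or absent unless
#'   `overwrite`).
#' @param overwrite Allow writing into an existing directory.
#' @return Invisibly, a list with the in-memory results: `db`, `stats`,
#'   `stats_aggregated`, `species_pairs`, `genus_richness`, `rate_fits`,
#'   `truth` (synthetic runs), `log`.
#' @export
run_pipeline <- function(config, outdir, overwrite = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(outdir) && length(dir(outdir)) && !overwrite)
    stop("output directory exists and is not empty: ", outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_add <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message("[seqcollide] ", line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  yaml::write_yaml(config_snapshot(config),
                   file.path(outdir, "run_config.yaml"))

  truth <- NULL
  db <- stage("input", {
    if (!is.null(config$synthetic)) {
      gen <- generate_synthetic_db(config$synthetic)
      truth <- gen$truth
      write_ground_truth(truth, file.path(outdir, "ground_truth.tsv"))
      gen$db
    } else {
      read_marker_fasta(config$fasta_paths, dialect = config$dialect)
    }
  })
  log_add("input: %d records, %d marker families", nrow(db$records),
          n_distinct(db$records$marker_id))

  if ("taxonomy" %in% config$filters) {
    res <- stage("filter_taxonomy", filter_taxonomy(db))
    write_filter_report(res$report,
                        file.path(outdir, "filter_taxonomy_report.tsv"))
    log_add("filter_taxonomy: %d -> %d records", nrow(db$records),
            nrow(res$db$records))
    db <- res$db
  }
  if ("length" %in% config$filters) {
    res <- stage("filter_length", filter_length(db))
    write_filter_report(res$report,
                        file.path(outdir, "filter_length_report.tsv"))
    log_add("filter_length: %d -> %d records", nrow(db$records),
            nrow(res$db$records))
    db <- res$db
  }
  if (config$write_fasta)
    write_marker_fasta(db, file.path(outdir, "filtered_fasta"), "silva")

  spec <- subsample_spec(config$sizes, config$n_replicates,
                         seed = config$seed, nested = config$nested)
  manifest <- stage("subsample", subsample_db(db, spec))
  write_subsample_manifest(manifest, file.path(outdir, "subsets.tsv"))
  log_add("subsample: %d subsets over %d sizes x %d replicates",
          nrow(distinct(manifest, .data$marker_id, .data$size,
                        .data$replicate)),
          length(spec$sizes), spec$n_replicates)

  labels <- db$records[, c("record_id", "species", "genus")]
  rec_index <- db$records[, c("record_id", "sequence")]
  if (config$write_clusterings)
    dir.create(file.path(outdir, "clusterings"), showWarnings = FALSE)

  subsets <- distinct(manifest, .data$marker_id, .data$size,
                      .data$replicate)
  stats_rows <- vector("list", nrow(subsets) * length(config$thresholds))
  final_clusterings <- list()  # largest size, replicate 1, per marker x thr
  pair_clusterings <- list()
  si <- 0L
  for (i in seq_len(nrow(subsets))) {
    mk <- subsets$marker_id[i]; sz <- subsets$size[i]
    rp <- subsets$replicate[i]
    ids <- manifest$record_id[manifest$marker_id == mk &
                                manifest$size == sz &
                                manifest$replicate == rp]
    recs <- rec_index[match(ids, rec_index$record_id), ]
    for (th in config$thresholds) {
      clu <- stage("cluster", greedy_cluster(recs, th))
      si <- si + 1L
      stats_rows[[si]] <- collision_summary(clu, labels, marker_id = mk,
                                            db_size = sz, replicate = rp,
                                            threshold = th)
      if (rp == 1L) pair_clusterings[[length(pair_clusterings) + 1L]] <- clu
      if (rp == 1L && sz == max(subsets$size[subsets$marker_id == mk]))
        final_clusterings[[paste(mk, th, sep = "@")]] <- clu
      if (config$write_clusterings) {
        base <- sprintf("%s_s%d_r%d_t%s", mk, sz, rp,
                        format(100 * th, trim = TRUE))
        write_clstr(clu, recs,
                    file.path(outdir, "clusterings",
                              paste0(base, ".clstr")))
      }
    }
  }
  stats <- bind_rows(stats_rows)
  write_tsv_plain(stats, file.path(outdir, "collision_stats.tsv"))
  log_add("cluster+stats: %d stat rows (%d thresholds)", nrow(stats),
          length(config$thresholds))

  stats_agg <- aggregate_collision_stats(stats, config$aggregate)
  write_tsv_plain(stats_agg,
                  file.path(outdir, "collision_stats_aggregated.tsv"))

  pairs <- stage("species_pairs",
                 species_pair_counts(pair_clusterings, labels))
  write_tsv_plain(pairs, file.path(outdir, "species_pairs.tsv"))
  log_add("species_pairs: %d colliding pairs", nrow(pairs))

  gr_rows <- list()
  for (key in names(final_clusterings)) {
    parts <- strsplit(key, "@", fixed = TRUE)[[1]]
    gr <- stage("genus_richness",
                genus_richness_relation(final_clusterings[[key]], labels))
    gr_rows[[key]] <- gr$points %>%
      mutate(marker_id = parts[1], threshold = as.numeric(parts[2]),
             correlation = as.numeric(gr$correlation))
  }
  genus_richness <- bind_rows(gr_rows)
  write_tsv_plain(genus_richness, file.path(outdir, "genus_richness.tsv"))

  fits <- stage("rate_fit",
                fit_all(stats, on = if (config$aggregate == "median")
                  "median" else "all"))
  write_rate_fits(fits, file.path(outdir, "rate_fits.tsv"))
  log_add("rate_fit: %d fits, %d undefined", nrow(fits), sum(!fits$ok))

  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(list(db = db, stats = stats, stats_aggregated = stats_agg,
                 species_pairs = pairs, genus_richness = genus_richness,
                 rate_fits = fits, truth = truth, log = log_lines))
}
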