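#' Specification of a database-growth subsampling experiment
#'
#' Defines the size grid and replication of the simulated databases: for
#' each marker family, random subsets of the stated sizes are drawn without
#' replacement, `n_replicates` times.  The reference experiments use sizes
#' 10,000 to 200,000 in 10,000-sequence steps (16S/GTDB scale) or 1,000 to
#' 5,000 in 1,000-sequence steps with 100 bootstrap replicates (single-genus
#' scale).
#'
#' @param sizes Strictly increasing subset sizes.
#' @param n_replicates Replicates per size.
#' @param seed Master seed; each subset's RNG seed is derived as a stable
#'   hash of `(seed, marker, size, replicate)`, so subsets are independent
#'   of evaluation order and reproducible in isolation.
#' @param nested If `TRUE`, within a replicate each size is a superset of
#'   the previous one (a single permutation per replicate, prefix-sliced);
#'   the default draws each size independently.
#' @return An object of class `subsample_spec`.
#' @export
subsample_spec <- function(sizes, n_replicates = 1L, seed = 1L,
                           nested = FALSE) {
  sizes <- as.integer(sizes)
  if (any(diff(sizes) <= 0) || any(sizes < 1L))
    stop("sizes must be strictly increasing positive integers")
  stopifnot(n_replicates >= 1L)
  structure(list(sizes = sizes, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), nested = isTRUE(nested)),
            class = "subsample_spec")
}

# One subset of record ids for (marker, size, replicate), reproducible from
# the spec alone.
subsample_ids <- function(ids, size, replicate, spec, marker) {
  n <- length(ids)
  if (size > n) return(NULL)
  if (spec$nested) {
    child <- stable_hash(spec$seed, marker, "nested", replicate)
    perm <- with_seed(child, sample.int(n, n))
    ids[perm[seq_len(size)]]
  } else {
    child <- stable_hash(spec$seed, marker, size, replicate)
    ids[with_seed(child, sample.int(n, size))]
  }
}

#' Draw the simulated databases for each marker family
#'
#' Subsets are drawn uniformly without replacement from each family's
#' *records* (not unique sequences), so duplicated sequences present in the
#' non-deduplicated source remain possible within a subset.  Sizes larger
#' than a family's record count are skipped with a warning and listed in the
#' `skipped` attribute.
#'
#' @param db A [marker_db()].
#' @param spec A [subsample_spec()].
#' @param markers Optional subset of marker families to process.
#' @return Tibble (`marker_id`, `size`, `replicate`, `record_id`), one row
#'   per sampled record; attribute `skipped` is a tibble of skipped
#'   (marker, size) combinations.
#' @export
subsample_db <- function(db, spec, markers = NULL) {
  stopifnot(inherits(spec, "subsample_spec"))
  r <- db$records
  if (is.null(markers)) markers <- unique(r$marker_id)
  out <- list(); skipped <- list()
  for (mk in markers) {
    ids <- r$record_id[r$marker_id == mk]
    for (size in spec$sizes) {
      if (size > length(ids)) {
        warning(sprintf("marker %s: size %d exceeds %d records, skipped",
                        mk, size, length(ids)))
        skipped[[length(skipped) + 1L]] <-
          tibble(marker_id = mk, size = size,
                 reason = sprintf("only %d records", length(ids)))
        next
      }
      for (rep_i in seq_len(spec$n_replicates)) {
        sel <- subsample_ids(ids, size, rep_i, spec, mk)
        out[[length(out) + 1L]] <- tibble(
          marker_id = mk, size = size, replicate = rep_i, record_id = sel)
      }
    }
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(marker_id = character(), size = integer(), replicate = integer(),
           record_id = character())
  attr(res, "skipped") <- if (length(skipped)) bind_rows(skipped) else
    tibble(marker_id = character(), size = integer(), reason = character())
  res
}

#' Write subset manifests as TSV
#' @param manifest Output of [subsample_db()].
#' @param path Output TSV path.
#' @export
write_subsample_manifest <- function(manifest, path) {
  write_tsv_plain(manifest, path)
}

#' Write each subset as its own FASTA file
#'
#' Materializes the subsets listed in a manifest as plain multi-FASTA
#' (SILVA-dialect headers), one file per (marker, size, replicate), named
#' `<marker>_s<size>_r<replicate>.fasta`.
#'
#' @param db The [marker_db()] the manifest was drawn from.
#' @param manifest Output of [subsample_db()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_subset_fasta <- function(db, manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  groups <- distinct(manifest, .data$marker_id, .data$size,
                     .data$replicate)
  paths <- character(nrow(groups))
  for (i in seq_len(nrow(groups))) {
    ids <- manifest$record_id[manifest$marker_id == groups$marker_id[i] &
                                manifest$size == groups$size[i] &
                                manifest$replicate == groups$replicate[i]]
    sub <- db$records[match(ids, db$records$record_id), ]
    lin <- apply(as.matrix(sub[, RANKS]), 1L, format_silva_lineage)
    ss <- Biostrings::BStringSet(sub$sequence)
    names(ss) <- paste(sub$record_id, lin)
    paths[i] <- file.path(dir, sprintf("%s_s%d_r%d.fasta",
                                       groups$marker_id[i], groups$size[i],
                                       groups$replicate[i]))
    Biostrings::writeXStringSet(ss, paths[i])
  }
  invisible(paths)
}
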