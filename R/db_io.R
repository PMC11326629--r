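RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' A marker-gene database
#'
#' A light container holding one tibble of taxonomically labeled marker-gene
#' records (columns `record_id`, `genome_id`, `marker_id`, the seven rank
#' columns `domain` ... `species`, `sequence`, `length`, and a logical
#' `complete` flag when parsed from FASTA) plus a provenance note listing the
#' source and the filters applied.  Records are grouped by `marker_id`; the
#' database is deliberately *not* deduplicated — identical sequences from
#' the same or different species are kept as separate records, as in the
#' reference databases this models.
#'
#' @param records Tibble of records; `record_id` must be unique and
#'   sequences non-empty.
#' @param provenance Character vector of provenance notes.
#' @return An object of class `marker_db`.
#' @export
marker_db <- function(records, provenance = character()) {
  records <- as_tibble(records)
  stopifnot(all(c("record_id", "marker_id", "sequence") %in% names(records)))
  if (anyDuplicated(records$record_id))
    stop("record_ids must be unique within a database")
  if (nrow(records) && any(!nzchar(records$sequence)))
    stop("sequences must be non-empty")
  if (!"length" %in% names(records)) records$length <- nchar(records$sequence)
  stopifnot(all(records$length == nchar(records$sequence)))
  structure(list(records = records, provenance = provenance),
            class = "marker_db")
}

#' @export
print.marker_db <- function(x, ...) {
  cat(sprintf("<marker_db> %d records, %d marker families, %d species\n",
              nrow(x$records), n_distinct(x$records$marker_id),
              n_distinct(x$records$species[!is.na(x$records$species)])))
  for (p in x$provenance) cat(" -", p, "\n")
  invisible(x)
}

#' Number of records per marker family
#' @param db A [marker_db()].
#' @return Tibble (`marker_id`, `n_records`).
#' @export
db_census <- function(db) {
  count(db$records, .data$marker_id, name = "n_records")
}

# Parse one SILVA-style lineage string ("Domain;Phylum;...;Genus species")
# into the seven ranks.  Returns a character(7) with NA for missing ranks.
parse_silva_lineage <- function(lineage) {
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  out <- rep(NA_character_, 7L)
  n <- min(length(parts), 7L)
  if (n > 0) out[seq_len(n)] <- parts[seq_len(n)]
  out[!nzchar(out) | is.na(out)] <- NA_character_
  out
}

format_silva_lineage <- function(ranks) {
  paste(ifelse(is.na(ranks), "", ranks), collapse = ";")
}

#' Read a marker-gene FASTA database with taxonomy-bearing headers
#'
#' Understands three header dialects:
#' * `silva`: `"<id> Domain;Phylum;Class;Order;Family;Genus;Genus species"`;
#'   a lineage is complete iff all seven ranks are present and non-empty.
#' * `gtdb`: `"<id> marker=<family> s__Genus species"`; the marker family is
#'   taken from the `marker=` field, genus is derived from the binomial, and
#'   the lineage counts as complete iff the `s__` field holds a binomial of
#'   at least two words (no ranks above genus are carried by this dialect).
#' * `generic`: the full description is tried as a SILVA lineage; otherwise
#'   the record is kept with an incomplete lineage.
#'
#' Records whose header cannot be parsed under the dialect are retained with
#' `complete = FALSE` and reported in the `unparsed` attribute, never
#' silently dropped.
#'
#' @param paths One or more FASTA files (plain or gzip); with the `silva`
#'   and `generic` dialects each file is one marker family named after the
#'   file unless `marker_id` is given.
#' @param dialect `"silva"`, `"gtdb"` or `"generic"`.
#' @param marker_id Optional marker family name override (recycled).
#' @return A [marker_db()]; attribute `unparsed` holds a tibble of record
#'   ids whose headers failed to parse.
#' @export
read_marker_fasta <- function(paths, dialect = c("silva", "gtdb", "generic"),
                              marker_id = NULL) {
  dialect <- match.arg(dialect)
  all_recs <- vector("list", length(paths))
  unparsed <- list()
  for (i in seq_along(paths)) {
    path <- paths[[i]]
    if (!file.exists(path)) stop("file not found: ", path)
    check_fasta_wellformed(path)
    ss <- Biostrings::readBStringSet(path)
    headers <- names(ss)
    seqs <- unname(as.character(ss))
    id <- sub("[ \t].*$", "", headers)
    desc <- ifelse(grepl("[ \t]", headers),
                   sub("^[^ \t]+[ \t]+", "", headers), "")
    file_marker <- if (!is.null(marker_id)) rep_len(marker_id,
                                                    length(paths))[i]
      else sub("\\.(fa|fasta|fna|faa)(\\.gz)?$", "", basename(path))
    rk <- matrix(NA_character_, nrow = length(id), ncol = 7L,
                 dimnames = list(NULL, RANKS))
    mk <- rep(file_marker, length(id))
    ok <- rep(TRUE, length(id))
    if (dialect %in% c("silva", "generic")) {
      has_lineage <- grepl(";", desc, fixed = TRUE)
      for (j in seq_along(id)) {
        if (has_lineage[j]) rk[j, ] <- parse_silva_lineage(desc[j])
      }
      ok <- has_lineage
      complete <- apply(rk, 1L, function(r) all(!is.na(r)))
    } else {
      m <- regmatches(desc, regexec("marker=(\\S+)\\s+s__(.+)$", desc))
      for (j in seq_along(id)) {
        if (length(m[[j]]) == 3L) {
          mk[j] <- m[[j]][2]
          sp <- trimws(m[[j]][3])
          rk[j, "species"] <- sp
          words <- strsplit(sp, "\\s+")[[1]]
          if (length(words) >= 2L) rk[j, "genus"] <- words[1]
        } else {
          ok[j] <- FALSE
        }
      }
      complete <- !is.na(rk[, "species"]) &
        vapply(strsplit(ifelse(is.na(rk[, "species"]), "",
                               rk[, "species"]), "\\s+"),
               length, integer(1)) >= 2L
    }
    if (dialect == "generic") ok <- rep(TRUE, length(id))
    recs <- as_tibble(rk)
    recs <- tibble(record_id = id, genome_id = NA_character_,
                   marker_id = mk) %>%
      dplyr::bind_cols(recs) %>%
      mutate(sequence = seqs, length = nchar(seqs), complete = complete)
    if (dialect == "silva") {
      bad <- which(!ok)
      if (length(bad))
        unparsed[[length(unparsed) + 1L]] <-
          tibble(record_id = id[bad], path = path,
                 reason = "no semicolon-delimited lineage in header")
    } else if (dialect == "gtdb") {
      bad <- which(!ok)
      if (length(bad))
        unparsed[[length(unparsed) + 1L]] <-
          tibble(record_id = id[bad], path = path,
                 reason = "no marker=/s__ fields in header")
    }
    all_recs[[i]] <- recs
  }
  records <- bind_rows(all_recs)
  db <- marker_db(records,
                  provenance = sprintf("read %d records from %d file(s), dialect=%s",
                                       nrow(records), length(paths), dialect))
  attr(db, "unparsed") <- if (length(unparsed)) bind_rows(unparsed) else
    tibble(record_id = character(), path = character(), reason = character())
  db
}

# Cheap well-formedness scan: first non-blank line must open a record.
check_fasta_wellformed <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  ln <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("format error: ", path, " is empty")
    ln <- ln + 1L
    if (nzchar(trimws(line))) {
      if (!startsWith(line, ">"))
        stop(sprintf("format error in %s at line %d: expected '>'", path, ln))
      break
    }
  }
  invisible(TRUE)
}

#' Remove records with incomplete taxonomy or organelle lineages
#'
#' Drops records whose lineage is incomplete for their dialect (see
#' [read_marker_fasta()]) and records whose lineage contains an organelle
#' keyword (case-insensitive `mitochondri*`, `chloroplast`, `plastid` at any
#' rank) — the taxonomic filter applied to 16S reference databases before
#' simulation.  Optionally, placeholder species labels (e.g. "uncultured",
#' "unidentified", "metagenome") can also be treated as incomplete.
#'
#' @param db A [marker_db()]; records lacking a `complete` column are
#'   assessed from the rank columns (all seven present).
#' @param drop_placeholders Treat placeholder species labels as incomplete
#'   (default `FALSE`).
#' @return List with `db` (filtered) and `report` (tibble `marker_id`,
#'   `reason`, `n_removed`).  Organelle removal takes precedence over
#'   incompleteness when both apply.
#' @export
filter_taxonomy <- function(db, drop_placeholders = FALSE) {
  r <- db$records
  if (!nrow(r)) {
    return(list(db = db, report = tibble(marker_id = character(),
                                         reason = character(),
                                         n_removed = integer())))
  }
  rank_mat <- as.matrix(r[, RANKS])
  organelle <- apply(rank_mat, 1L, function(x)
    any(grepl("mitochondri|chloroplast|plastid", x, ignore.case = TRUE),
        na.rm = TRUE))
  if ("complete" %in% names(r)) {
    complete <- r$complete
  } else {
    complete <- apply(rank_mat, 1L, function(x) all(!is.na(x) & nzchar(x)))
  }
  if (drop_placeholders) {
    ph <- grepl("uncultured|unidentified|unknown|metagenome",
                ifelse(is.na(r$species), "", r$species), ignore.case = TRUE)
    complete <- complete & !ph
  }
  drop_org <- organelle
  drop_inc <- !complete & !organelle
  keep <- !(drop_org | drop_inc)
  report <- bind_rows(
    r[drop_org, ] %>% count(.data$marker_id, name = "n_removed") %>%
      mutate(reason = "organelle"),
    r[drop_inc, ] %>% count(.data$marker_id, name = "n_removed") %>%
      mutate(reason = "incomplete_taxonomy")
  ) %>% select("marker_id", "reason", "n_removed")
  out <- marker_db(r[keep, ],
                   provenance = c(db$provenance,
                                  sprintf("filter_taxonomy: removed %d of %d",
                                          sum(!keep), nrow(r))))
  list(db = out, report = report)
}

#' Remove length-artifact records (half-to-twice band around the family mean)
#'
#' Per marker family, computes the arithmetic mean record length once on the
#' unfiltered family and retains records with
#' `mean/2 <= length <= 2 * mean`.  The band is not recomputed after removal
#' (single pass), so records near the boundary of a family whose mean was
#' dragged by extreme artifacts are judged against the pre-filter mean.
#'
#' @param db A [marker_db()].
#' @return List with `db` (filtered) and `report` (tibble `marker_id`,
#'   `reason = "length"`, `n_removed`, `mean_length`, `lower`, `upper`).
#' @export
filter_length <- function(db) {
  r <- db$records
  if (!nrow(r)) {
    return(list(db = db, report = tibble(marker_id = character(),
                                         reason = character(),
                                         n_removed = integer(),
                                         mean_length = double(),
                                         lower = double(), upper = double())))
  }
  bands <- r %>% group_by(.data$marker_id) %>%
    summarise(mean_length = mean(.data$length),
              lower = .data$mean_length / 2,
              upper = .data$mean_length * 2, .groups = "drop")
  r2 <- left_join(r, bands, by = "marker_id")
  keep <- r2$length >= r2$lower & r2$length <= r2$upper
  report <- r2[!keep, ] %>% count(.data$marker_id, name = "n_removed") %>%
    mutate(reason = "length") %>%
    left_join(bands, by = "marker_id") %>%
    select("marker_id", "reason", "n_removed", "mean_length", "lower",
           "upper")
  out <- marker_db(r[keep, ],
                   provenance = c(db$provenance,
                                  sprintf("filter_length: removed %d of %d",
                                          sum(!keep), nrow(r))))
  list(db = out, report = report)
}

#' Write a marker database as multi-FASTA, one file per marker family
#'
#' @param db A [marker_db()].
#' @param dir Output directory (created if needed).
#' @param dialect Header dialect: `"silva"` writes
#'   `"<id> Domain;...;Genus species"`, `"gtdb"` writes
#'   `"<id> marker=<family> s__Genus species"`.
#' @return Invisibly, the written file paths (named by marker family).
#' @export
write_marker_fasta <- function(db, dir, dialect = c("silva", "gtdb")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- db$records
  paths <- character(0)
  for (mk in unique(r$marker_id)) {
    sub <- r[r$marker_id == mk, ]
    headers <- if (dialect == "silva") {
      lin <- apply(as.matrix(sub[, RANKS]), 1L, format_silva_lineage)
      paste(sub$record_id, lin)
    } else {
      sprintf("%s marker=%s s__%s", sub$record_id, sub$marker_id,
              sub$species)
    }
    ss <- Biostrings::BStringSet(sub$sequence)
    names(ss) <- headers
    path <- file.path(dir, paste0(mk, ".fasta"))
    Biostrings::writeXStringSet(ss, path)
    paths[mk] <- path
  }
  invisible(paths)
}

#' Write a filter report as TSV
#' @param report A report tibble from [filter_taxonomy()] or
#'   [filter_length()].
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  write_tsv_plain(report, path)
}
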