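msc_ids <- function(clustering, labels) {
  cl <- left_join(clustering$clusters,
                  labels[, intersect(c("record_id", "species", "genus"),
                                     names(labels))],
                  by = "record_id")
  if (any(is.na(cl$species)))
    stop("input error: unlabeled record(s): ",
         paste(head(cl$record_id[is.na(cl$species)], 3), collapse = ", "))
  cl
}

#' Multi-species-cluster summary of one clustering
#'
#' A cluster is *multi-species* when it contains sequences labeled with two
#' or more distinct species — the unit of taxonomic ambiguity: a classifier
#' cannot separate the species co-occurring in such a cluster.  Counts are
#' over sequence records, so duplicated sequences from the same species each
#' count (the source databases are not deduplicated).  The species universe
#' for the percentage is the set of species present in the clustered
#' (sub)database, not in its full source.
#'
#' @param clustering A [greedy_cluster()] result.
#' @param labels Tibble `record_id`, `species` covering every clustered
#'   record.
#' @param marker_id,db_size,replicate,threshold Metadata carried into the
#'   output row; `db_size` defaults to the clustered record count and
#'   `threshold` to the clustering's.
#' @return One-row tibble: `marker_id`, `db_size`, `replicate`, `threshold`,
#'   `n_clusters`, `n_multi_species_clusters`, `n_sequences_in_msc`,
#'   `n_species_total`, `n_species_in_msc`, `pct_species_in_msc`.
#' @export
collision_summary <- function(clustering, labels, marker_id = NA_character_,
                              db_size = clustering$n_records,
                              replicate = NA_integer_,
                              threshold = clustering$threshold) {
  cl <- msc_ids(clustering, labels)
  per_cluster <- cl %>% group_by(.data$cluster_id) %>%
    summarise(n_seq = n(), n_species = n_distinct(.data$species),
              .groups = "drop")
  msc <- per_cluster$cluster_id[per_cluster$n_species >= 2L]
  in_msc <- cl[cl$cluster_id %in% msc, ]
  n_species_total <- n_distinct(cl$species)
  n_species_in_msc <- n_distinct(in_msc$species)
  tibble(
    marker_id = marker_id,
    db_size = as.integer(db_size),
    replicate = as.integer(replicate),
    threshold = threshold,
    n_clusters = nrow(per_cluster),
    n_multi_species_clusters = length(msc),
    n_sequences_in_msc = nrow(in_msc),
    n_species_total = n_species_total,
    n_species_in_msc = n_species_in_msc,
    pct_species_in_msc = 100 * n_species_in_msc / n_species_total
  )
}

#' Species-pair co-occurrence counts in multi-species clusters
#'
#' For every multi-species cluster, each unordered pair of distinct species
#' present in it is counted once per cluster (not once per sequence pair),
#' aggregated over the supplied clusterings — the table of which species
#' pairs collide most often.
#'
#' @param clusterings One [greedy_cluster()] result or a list of them.
#' @param labels Tibble `record_id`, `species`.
#' @return Tibble (`species_a`, `species_b`, `n_cooccurrences`) with
#'   `species_a < species_b`, sorted by descending count.
#' @export
species_pair_counts <- function(clusterings, labels) {
  if (inherits(clusterings, "clustering")) clusterings <- list(clusterings)
  pairs <- list()
  for (clu in clusterings) {
    cl <- msc_ids(clu, labels)
    sp_by_cluster <- cl %>% distinct(.data$cluster_id, .data$species) %>%
      group_by(.data$cluster_id) %>%
      summarise(sp = list(sort(.data$species)), .groups = "drop")
    for (sp in sp_by_cluster$sp) {
      if (length(sp) < 2L) next
      cmb <- utils::combn(sp, 2L)
      pairs[[length(pairs) + 1L]] <-
        tibble(species_a = cmb[1, ], species_b = cmb[2, ])
    }
  }
  if (!length(pairs)) {
    return(tibble(species_a = character(), species_b = character(),
                  n_cooccurrences = integer()))
  }
  bind_rows(pairs) %>%
    count(.data$species_a, .data$species_b, name = "n_cooccurrences") %>%
    arrange(dplyr::desc(.data$n_cooccurrences), .data$species_a,
            .data$species_b)
}

#' Relation between genus species-richness and collision involvement
#'
#' For each species of one designated clustering (by convention the largest
#' simulated database size — the final iteration of the growth experiment),
#' tabulates the species richness of its genus (distinct congeneric species
#' in the clustered database) and the number of multi-species clusters
#' containing at least one of its sequences, and reports the Pearson
#' correlation between the two — positive when species-rich genera drive
#' collisions.
#'
#' @param clustering A [greedy_cluster()] result.
#' @param labels Tibble `record_id`, `species`, `genus`.
#' @return List with `points` (tibble `species`, `genus`, `genus_richness`,
#'   `n_msc_of_species`) and `correlation` (Pearson r; `NA` with an
#'   explanatory `reason` attribute when fewer than 3 points or zero
#'   variance).
#' @export
genus_richness_relation <- function(clustering, labels) {
  stopifnot("genus" %in% names(labels))
  cl <- msc_ids(clustering, labels)
  richness <- cl %>% distinct(.data$genus, .data$species) %>%
    count(.data$genus, name = "genus_richness")
  per_cluster <- cl %>% group_by(.data$cluster_id) %>%
    mutate(n_species_in_cluster = n_distinct(.data$species)) %>% ungroup()
  msc_per_species <- per_cluster %>%
    filter(.data$n_species_in_cluster >= 2L) %>%
    distinct(.data$species, .data$cluster_id) %>%
    count(.data$species, name = "n_msc_of_species")
  points <- cl %>% distinct(.data$species, .data$genus) %>%
    left_join(richness, by = "genus") %>%
    left_join(msc_per_species, by = "species") %>%
    mutate(n_msc_of_species = dplyr::coalesce(.data$n_msc_of_species, 0L)) %>%
    arrange(.data$species)
  correlation <- NA_real_
  if (nrow(points) < 3L) {
    attr(correlation, "reason") <- "fewer than 3 species"
  } else if (stats::sd(points$genus_richness) == 0 ||
             stats::sd(points$n_msc_of_species) == 0) {
    attr(correlation, "reason") <- "zero variance"
  } else {
    correlation <- cor(points$genus_richness, points$n_msc_of_species)
  }
  list(points = points, correlation = correlation)
}

#' Fraction of species colliding in at least k marker families
#'
#' Given one clustering per marker family over a shared species universe
#' (the union of species across families), the percentage of species that
#' occur in at least one multi-species cluster in `k` or more families —
#' species whose resolution is lost across much of the marker panel, not
#' just for a single unlucky gene.
#'
#' @param clusterings Named list of [greedy_cluster()] results, one per
#'   marker family.
#' @param labels Tibble `record_id`, `species` covering all records.
#' @param k Minimum number of families (1 to `length(clusterings)`).
#' @return Percentage (0-100).
#' @export
multi_marker_species_fraction <- function(clusterings, labels, k) {
  if (k > length(clusterings))
    stop("configuration error: k exceeds the number of marker families")
  stopifnot(k >= 1L)
  universe <- character(0)
  hits <- list()
  for (i in seq_along(clusterings)) {
    cl <- msc_ids(clusterings[[i]], labels)
    universe <- union(universe, unique(cl$species))
    sp_in_msc <- cl %>% group_by(.data$cluster_id) %>%
      filter(n_distinct(.data$species) >= 2L) %>% ungroup() %>%
      pull(.data$species) %>% unique()
    hits[[i]] <- sp_in_msc
  }
  n_fam <- table(unlist(hits))
  n_hit <- sum(n_fam >= k)
  100 * n_hit / length(universe)
}

#' Aggregate collision statistics across replicates
#'
#' Collapses a stats table (one row per marker, size, replicate and
#' threshold, from [collision_summary()]) to one row per marker, size and
#' threshold, reporting the replicate median (the convention of the growth
#' figures) or mean of every count column, plus the 25/75% quantiles of the
#' number of sequences in multi-species clusters.
#'
#' @param stats Row-bound [collision_summary()] output.
#' @param method `"median"` or `"mean"`.
#' @return Aggregated tibble.
#' @export
aggregate_collision_stats <- function(stats, method = c("median", "mean")) {
  method <- match.arg(method)
  f <- if (method == "median") median else mean
  stats %>%
    group_by(.data$marker_id, .data$db_size, .data$threshold) %>%
    summarise(
      n_replicates = n(),
      q25_sequences_in_msc = stats::quantile(.data$n_sequences_in_msc, 0.25),
      q75_sequences_in_msc = stats::quantile(.data$n_sequences_in_msc, 0.75),
      n_clusters = f(.data$n_clusters),
      n_multi_species_clusters = f(.data$n_multi_species_clusters),
      n_sequences_in_msc = f(.data$n_sequences_in_msc),
      n_species_total = f(.data$n_species_total),
      n_species_in_msc = f(.data$n_species_in_msc),
      pct_species_in_msc = f(.data$pct_species_in_msc),
      .groups = "drop"
    )
}
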