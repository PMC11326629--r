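#' Full-coverage pairwise sequence identity
#'
#' Identity between two sequences under the clustering rule used throughout
#' the package: the shorter sequence `S` must align end-to-end against the
#' longer sequence `L` (end gaps on `L` are free), and
#' `identity = max(score, 0) / length(S)` where the alignment score counts
#' matches as +1, mismatches as 0 and every internal gap column as -1, so a
#' gap reduces identity at least as much as a mismatch.  Under this
#' convention `identity == 1` exactly when `S` is a substring of `L`.
#' Sequences are treated as opaque strings: nucleotide, protein and
#' ambiguity codes are compared verbatim.
#'
#' @param a,b Non-empty sequences (character scalars).
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("ACGT", "ACGT")     # 1
#' pairwise_identity("ACG", "TTACGTT")   # 1 (containment)
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L,
            length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("input error: empty sequence")
  .identity_cpp(a, b)
}

#' Greedy incremental identity clustering with the full-coverage rule
#'
#' Reimplements the classic greedy scheme of incremental clusterers such as
#' CD-HIT: records are sorted by length descending (ties broken
#' lexicographically by sequence, then by record id, so the result is a
#' function of the record *multiset* only), and each record in turn either
#' joins the first existing cluster — in cluster-creation order — whose
#' representative it meets at `>= threshold` identity with full coverage of
#' the shorter sequence (see [pairwise_identity()]), or founds a new
#' cluster.  Representatives therefore have maximal length within their
#' cluster, and no representative meets the threshold against any
#' earlier representative.  At `threshold = 1` the comparison reduces to
#' exact substring containment and is computed by a string-search fast
#' path; at lower thresholds a shared 8-mer screen rejects hopeless
#' candidate pairs before the dynamic-programming alignment (the screen is
#' conservative: it never rejects a pair the alignment would accept).
#'
#' @param records Tibble with columns `record_id` and `sequence` (extra
#'   columns are ignored).
#' @param threshold Identity threshold in (0, 1]; the reference thresholds
#'   are 0.95, 0.97, 0.99 and 1.
#' @return An object of class `clustering`: list with `clusters` (tibble
#'   `cluster_id`, `record_id`, `is_representative`, in cluster-creation
#'   order), `threshold`, `n_records`, `n_clusters`.
#' @examples
#' recs <- tibble::tibble(record_id = c("a", "b", "c"),
#'                        sequence = c("ACGTACGTACGT", "ACGTACGTACGT",
#'                                     "TTTTGGGGCCCC"))
#' greedy_cluster(recs, 1.0)  # a and b co-cluster, c is a singleton
#' @export
greedy_cluster <- function(records, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  records <- as_tibble(records)
  stopifnot(all(c("record_id", "sequence") %in% names(records)))
  if (!nrow(records)) stop("non-empty record set required")
  ord <- order(-nchar(records$sequence), records$sequence,
               records$record_id, method = "radix")
  seqs <- records$sequence[ord]
  ids <- records$record_id[ord]
  assign <- .greedy_cluster_cpp(seqs, threshold)
  is_rep <- !duplicated(assign)
  clusters <- tibble(cluster_id = as.integer(assign), record_id = ids,
                     is_representative = is_rep) %>%
    arrange(.data$cluster_id)
  structure(list(clusters = clusters, threshold = threshold,
                 n_records = nrow(records),
                 n_clusters = max(assign)),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat(sprintf("<clustering> %d records -> %d clusters at %.0f%% identity\n",
              x$n_records, x$n_clusters, 100 * x$threshold))
  invisible(x)
}

#' Brute-force verification of a clustering against its contract
#'
#' Recomputes, by direct pairwise alignment without any screening
#' heuristics, every constraint the greedy clusterer promises:
#' * `partition`: every input record is in exactly one cluster;
#' * `representative_length`: each representative has maximal length among
#'   its members;
#' * `member_threshold`: every member meets the identity threshold with
#'   full coverage against its representative;
#' * `representative_maximality`: no representative meets the threshold
#'   against any longer-or-equal representative of an earlier cluster.
#'
#' Violations are reported as rows, not raised as errors, so planted-defect
#' clusterings can be inspected.
#'
#' @param clustering A [greedy_cluster()] result (or a hand-built object of
#'   the same shape).
#' @param records The exact record tibble that was clustered.
#' @param threshold Identity threshold to verify against; defaults to
#'   `clustering$threshold`.
#' @return Tibble (`check`, `cluster_id`, `record_id`, `detail`); zero rows
#'   means the clustering satisfies its contract.
#' @export
verify_clustering <- function(clustering, records,
                              threshold = clustering$threshold) {
  cl <- clustering$clusters
  records <- as_tibble(records)
  viol <- list()
  bad <- function(check, cluster_id, record_id, detail) {
    viol[[length(viol) + 1L]] <<- tibble(
      check = check, cluster_id = as.integer(cluster_id),
      record_id = as.character(record_id), detail = detail)
  }

  if (anyDuplicated(cl$record_id))
    bad("partition", NA, cl$record_id[duplicated(cl$record_id)][1],
        "record in more than one cluster")
  missing <- setdiff(records$record_id, cl$record_id)
  for (m in missing) bad("partition", NA, m, "record missing from clustering")
  alien <- setdiff(cl$record_id, records$record_id)
  for (a in alien) bad("partition", NA, a, "clustered id not in input")

  seq_of <- stats::setNames(records$sequence, records$record_id)
  reps <- cl[cl$is_representative, ]
  reps <- reps[order(reps$cluster_id), ]
  rep_seq <- seq_of[reps$record_id]

  for (ci in reps$cluster_id) {
    rs <- rep_seq[[match(ci, reps$cluster_id)]]
    members <- cl$record_id[cl$cluster_id == ci & !cl$is_representative]
    for (mid in members) {
      ms <- seq_of[[mid]]
      if (nchar(ms) > nchar(rs))
        bad("representative_length", ci, mid,
            sprintf("member %d nt > representative %d nt",
                    nchar(ms), nchar(rs)))
      id <- pairwise_identity(ms, rs)
      if (id < threshold - 1e-12)
        bad("member_threshold", ci, mid,
            sprintf("identity %.4f < %.4f", id, threshold))
    }
  }
  nrep <- nrow(reps)
  if (nrep > 1L) {
    for (j in 2:nrep) {
      for (i in 1:(j - 1L)) {
        id <- pairwise_identity(rep_seq[[j]], rep_seq[[i]])
        if (id >= threshold - 1e-12)
          bad("representative_maximality", reps$cluster_id[j],
              reps$record_id[j],
              sprintf("meets earlier representative %s at %.4f",
                      reps$record_id[i], id))
      }
    }
  }
  if (length(viol)) bind_rows(viol) else
    tibble(check = character(), cluster_id = integer(),
           record_id = character(), detail = character())
}

#' Write a clustering in the CD-HIT .clstr dialect
#'
#' @param clustering A [greedy_cluster()] result.
#' @param records The clustered record tibble (for lengths and identities).
#' @param path Output `.clstr` path.
#' @return Invisibly, `path`.
#' @export
write_clstr <- function(clustering, records, path) {
  seq_of <- stats::setNames(records$sequence, records$record_id)
  cl <- clustering$clusters
  con <- file(path, "wt")
  on.exit(close(con))
  for (ci in sort(unique(cl$cluster_id))) {
    writeLines(sprintf(">Cluster %d", ci - 1L), con)
    sub <- cl[cl$cluster_id == ci, ]
    rep_id <- sub$record_id[sub$is_representative][1]
    k <- 0L
    for (j in seq_len(nrow(sub))) {
      rid <- sub$record_id[j]
      len <- nchar(seq_of[[rid]])
      if (rid == rep_id) {
        writeLines(sprintf("%d\t%dnt, >%s... *", k, len, rid), con)
      } else {
        idy <- 100 * pairwise_identity(seq_of[[rid]], seq_of[[rep_id]])
        writeLines(sprintf("%d\t%dnt, >%s... at %.2f%%", k, len, rid, idy),
                   con)
      }
      k <- k + 1L
    }
  }
  invisible(path)
}

#' Write a clustering as TSV with species labels
#'
#' @param clustering A [greedy_cluster()] result.
#' @param labels Tibble with `record_id` and `species` (optional).
#' @param path Output TSV path.
#' @export
write_cluster_tsv <- function(clustering, labels = NULL, path) {
  out <- clustering$clusters
  if (!is.null(labels))
    out <- left_join(out, labels[, intersect(c("record_id", "species"),
                                             names(labels))],
                     by = "record_id")
  write_tsv_plain(out, path)
}
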