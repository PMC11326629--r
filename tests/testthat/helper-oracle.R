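# Independent matrix-DP oracle for full-coverage identity, written directly
# from the scoring definition (match +1, mismatch 0, internal gap column -1,
# end gaps on the longer sequence free; identity = max(score, 0) / len(S)).
# Kept in plain R, separate from the package's compiled implementation.
identity_oracle <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  s <- strsplit(a, "")[[1]]
  l <- strsplit(b, "")[[1]]
  n <- length(s); m <- length(l)
  M <- matrix(NA_real_, n + 1L, m + 1L)
  M[1, ] <- 0                      # free leading end gap on L
  if (n >= 1) M[2:(n + 1), 1] <- -(1:n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(
        M[i, j] + as.integer(s[i] == l[j]),
        M[i, j + 1] - 1,
        M[i + 1, j] - 1)
    }
  }
  max(max(M[n + 1, ]), 0) / n      # free trailing end gap on L
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# A clustering test instance mixing unrelated sequences, point-mutated
# near-copies and substrings, so merges actually happen at the reference
# thresholds.
random_instance <- function(n, len_range = c(50, 500)) {
  seqs <- character(n)
  i <- 1L
  while (i <= n) {
    roll <- runif(1)
    if (roll < 0.45 || i == 1L) {
      seqs[i] <- random_seq(sample(len_range[1]:len_range[2], 1))
    } else if (roll < 0.8) {
      parent <- seqs[sample.int(i - 1L, 1)]
      ch <- strsplit(parent, "")[[1]]
      nmut <- rbinom(1, length(ch), runif(1, 0, 0.08))
      if (nmut > 0) {
        at <- sample.int(length(ch), min(nmut, length(ch)))
        ch[at] <- sample(c("A", "C", "G", "T"), length(at), replace = TRUE)
      }
      seqs[i] <- paste(ch, collapse = "")
    } else {
      parent <- seqs[sample.int(i - 1L, 1)]
      plen <- nchar(parent)
      keep <- sample(seq.int(max(1, plen %/% 2), plen), 1)
      start <- sample.int(plen - keep + 1L, 1)
      seqs[i] <- substr(parent, start, start + keep - 1L)
    }
    i <- i + 1L
  }
  tibble::tibble(record_id = sprintf("r%04d", seq_len(n)), sequence = seqs)
}

# Minimal labeled record set for stats tests: one record per element of
# `species`, sequence chosen so that clustering groups records as `groups`
# dictates (same group letter -> identical sequence).
labeled_records <- function(species, groups) {
  stopifnot(length(species) == length(groups))
  pool <- vapply(seq_along(unique(groups)), function(i)
    random_seq(60), character(1))
  names(pool) <- unique(groups)
  tibble::tibble(
    record_id = sprintf("x%03d", seq_along(species)),
    sequence = pool[groups],
    species = species,
    genus = sub(" .*$", "", species))
}
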