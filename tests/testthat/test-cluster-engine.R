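test_that("pairwise identity handles the canonical cases", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1.0)
  expect_equal(pairwise_identity("ACG", "TTACGTT"), 1.0)  # containment
  expect_equal(pairwise_identity("TTACGTT", "ACG"), 1.0)  # symmetric
  # one mismatch over the 4-residue shorter sequence
  expect_equal(pairwise_identity("ACGT", "AGGTTTTT"), 0.75)
  expect_error(pairwise_identity("", "ACGT"), "empty")
})

test_that("identity equals the exhaustive DP oracle on random short pairs", {
  set.seed(101)
  for (i in 1:300) {
    a <- random_seq(sample(1:12, 1))
    b <- random_seq(sample(1:12, 1))
    expect_equal(pairwise_identity(a, b), identity_oracle(a, b),
                 info = paste(a, b))
  }
})

test_that("identity agrees with an independent aligner under the same scoring", {
  # Biostrings global-local alignment with match=1, mismatch=0,
  # gapOpening=0, gapExtension=1 maximises matches - gap columns, the
  # package's scoring, with free end gaps on the subject
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = TRUE)
  set.seed(55)
  for (i in 1:40) {
    a <- random_seq(sample(5:60, 1))
    b <- random_seq(sample(5:60, 1))
    s <- if (nchar(a) <= nchar(b)) a else b
    l <- if (nchar(a) <= nchar(b)) b else a
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(s), subject = Biostrings::DNAString(l),
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 1,
      type = "global-local")
    expect_equal(pairwise_identity(a, b),
                 max(Biostrings::score(aln), 0) / nchar(s),
                 info = paste(a, b))
  }
})

test_that("banded join decision agrees with the full DP", {
  set.seed(66)
  for (i in 1:250) {
    n <- sample(20:200, 1)
    a <- random_seq(n)
    ch <- strsplit(a, "")[[1]]
    nm <- rbinom(1, n, runif(1, 0, 0.12))
    if (nm > 0) {
      at <- sample(n, nm)
      ch[at] <- sample(c("A", "C", "G", "T"), nm, replace = TRUE)
    }
    if (runif(1) < 0.3) ch <- ch[-sample(length(ch), sample(1:3, 1))]
    b <- paste(ch, collapse = "")
    for (t in c(0.95, 0.97, 0.99, 1.0)) {
      expect_identical(seqcollide:::.identity_at_least_cpp(a, b, t),
                       pairwise_identity(a, b) >= t - 1e-12,
                       info = sprintf("n=%d t=%.2f", n, t))
    }
  }
})

test_that("greedy clustering merges what it must and only that", {
  # identical sequences from two species co-cluster at threshold 1
  recs <- tibble::tibble(record_id = c("a", "b"),
                         sequence = c("ACGTACGTACGT", "ACGTACGTACGT"))
  clu <- greedy_cluster(recs, 1.0)
  expect_equal(clu$n_clusters, 1L)
  # sequences with no shared residues stay apart at any threshold
  recs2 <- tibble::tibble(record_id = c("a", "b"),
                          sequence = c("AAAAAAAA", "CCCCCCCC"))
  for (th in c(0.95, 0.97, 0.99, 1.0)) {
    expect_equal(greedy_cluster(recs2, th)$n_clusters, 2L)
  }
})

test_that("clustering satisfies its contract on random instances", {
  set.seed(77)
  for (i in 1:8) {
    recs <- random_instance(50)
    for (th in c(0.95, 0.97, 0.99, 1.0)) {
      clu <- greedy_cluster(recs, th)
      v <- verify_clustering(clu, recs)
      expect_equal(nrow(v), 0L, info = sprintf("instance %d thr %.2f", i, th))
    }
  }
})

test_that("clustering is invariant to input record order", {
  set.seed(88)
  recs <- random_instance(60)
  shuffled <- recs[sample.int(nrow(recs)), ]
  for (th in c(0.97, 1.0)) {
    c1 <- greedy_cluster(recs, th)
    c2 <- greedy_cluster(shuffled, th)
    expect_identical(c1$clusters, c2$clusters)
  }
})

test_that("cluster count is non-increasing as the threshold loosens", {
  set.seed(99)
  for (i in 1:100) {
    recs <- random_instance(25, len_range = c(40, 120))
    counts <- vapply(c(1.0, 0.99, 0.97, 0.95), function(th)
      greedy_cluster(recs, th)$n_clusters, numeric(1))
    expect_true(all(diff(counts) <= 0), info = paste("instance", i))
  }
})

test_that("byte-identical sequences always co-cluster at threshold 1", {
  set.seed(111)
  recs <- random_instance(40)
  recs$sequence[31:40] <- recs$sequence[1:10]  # plant exact duplicates
  clu <- greedy_cluster(recs, 1.0)
  asg <- stats::setNames(clu$clusters$cluster_id, clu$clusters$record_id)
  for (i in 1:10) {
    expect_equal(unname(asg[recs$record_id[i]]),
                 unname(asg[recs$record_id[30 + i]]))
  }
})

test_that("verifier reports planted contract violations", {
  recs <- tibble::tibble(
    record_id = c("r1", "r2", "r3"),
    sequence = c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTACGTAC"))
  # identical pair split across clusters at threshold 1 -> maximality
  fake <- structure(list(
    clusters = tibble::tibble(cluster_id = c(1L, 2L, 3L),
                              record_id = c("r3", "r1", "r2"),
                              is_representative = TRUE),
    threshold = 1.0, n_records = 3L, n_clusters = 3L),
    class = "clustering")
  v <- verify_clustering(fake, recs)
  expect_true("representative_maximality" %in% v$check)
  # representative shorter than a member -> length violation
  fake2 <- structure(list(
    clusters = tibble::tibble(cluster_id = c(1L, 1L),
                              record_id = c("r1", "r3"),
                              is_representative = c(TRUE, FALSE)),
    threshold = 1.0, n_records = 2L, n_clusters = 1L),
    class = "clustering")
  v2 <- verify_clustering(fake2, recs[c(1, 3), ])
  expect_true("representative_length" %in% v2$check)
})

test_that("clstr output follows the CD-HIT dialect", {
  recs <- tibble::tibble(record_id = c("long1", "short1"),
                         sequence = c("ACGTACGTACGT", "ACGTACGTAC"))
  clu <- greedy_cluster(recs, 0.95)
  path <- tempfile(fileext = ".clstr")
  write_clstr(clu, recs, path)
  lines <- readLines(path)
  expect_equal(lines[1], ">Cluster 0")
  expect_match(lines[2], "^0\t12nt, >long1\\.\\.\\. \\*$")
  expect_match(lines[3], "at 100\\.00%$")
})
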