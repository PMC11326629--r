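test_that("multi-species clusters are counted over records, not unique sequences", {
  set.seed(5)
  # clusters: {A,A}, {B} -> no msc
  r1 <- labeled_records(c("G a1", "G a1", "G b1"), c("x", "x", "y"))
  s1 <- collision_summary(greedy_cluster(r1, 1.0), r1)
  expect_equal(s1$n_clusters, 2L)
  expect_equal(s1$n_multi_species_clusters, 0L)
  expect_equal(s1$n_sequences_in_msc, 0L)

  # clusters: {A,B}, {A}, {C,C,D} -> 2 msc, 5 sequences, all 4 species
  r2 <- labeled_records(c("G a", "G b", "G a", "G c", "G c", "G d"),
                        c("p", "p", "q", "r", "r", "r"))
  s2 <- collision_summary(greedy_cluster(r2, 1.0), r2)
  expect_equal(s2$n_multi_species_clusters, 2L)
  expect_equal(s2$n_sequences_in_msc, 5L)
  expect_equal(s2$n_species_in_msc, 4L)
  expect_equal(s2$pct_species_in_msc, 100)
  # member counts over clusters account for every record
  expect_equal(s2$db_size, nrow(r2))
  expect_error(collision_summary(greedy_cluster(r2, 1.0),
                                 r2[1:3, ]), "unlabeled")
})

test_that("species pair counts use one increment per cluster per pair", {
  set.seed(6)
  r <- labeled_records(c("G a", "G b", "G c"), c("u", "u", "u"))
  pc <- species_pair_counts(greedy_cluster(r, 1.0), r)
  expect_equal(nrow(pc), 3L)
  expect_true(all(pc$n_cooccurrences == 1L))
  expect_true(all(pc$species_a < pc$species_b))

  # two clusterings with the same {A,B} cluster -> count 2
  clu <- greedy_cluster(r[1:2, ], 1.0)
  pc2 <- species_pair_counts(list(clu, clu), r)
  expect_equal(pc2$n_cooccurrences, 2L)
})

test_that("planted collisions dominate the species-pair table", {
  cfg <- synthetic_config(n_genera = 6, species_per_genus = 2,
                          genomes_per_species = 2,
                          inter_species_divergence = 0.3,
                          intra_species_divergence = 0,
                          collision_rate = 1, seed = 19)
  g <- generate_synthetic_db(cfg)
  clu <- greedy_cluster(g$db$records, 1.0)
  pc <- species_pair_counts(clu, g$db$records)
  planted <- g$truth$collisions
  expect_setequal(paste(pc$species_a, pc$species_b),
                  paste(planted$species_a, planted$species_b))
})

test_that("genus richness relation flags degenerate and planted structure", {
  set.seed(7)
  # all singleton clusters -> zero msc everywhere, correlation undefined
  r <- labeled_records(c("G a", "G b", "H c"), c("x", "y", "z"))
  gr <- genus_richness_relation(greedy_cluster(r, 1.0), r)
  expect_true(all(gr$points$n_msc_of_species == 0))
  expect_true(is.na(gr$correlation))
  expect_equal(attr(gr$correlation, "reason"), "zero variance")

  # collisions only in the species-rich genus
  sp <- c("R a", "R b", "R c", "R d", "R e", "P x", "P y")
  grp <- c("m", "m", "n", "n", "o", "p", "q")  # R-species collide pairwise
  r2 <- labeled_records(sp, grp)
  gr2 <- genus_richness_relation(greedy_cluster(r2, 1.0), r2)
  rich <- gr2$points[gr2$points$genus == "R", ]
  poor <- gr2$points[gr2$points$genus == "P", ]
  expect_true(all(poor$n_msc_of_species == 0))
  expect_equal(sum(rich$n_msc_of_species > 0), 4L)
  expect_gt(gr2$correlation, 0)
})

test_that("multi-marker species fraction applies the >= k families rule", {
  set.seed(8)
  # family f1: A and B collide; family f2: A and C collide
  f1 <- labeled_records(c("G a", "G b", "G c"), c("u", "u", "v"))
  f2 <- labeled_records(c("G a", "G b", "G c"), c("w", "x", "w"))
  clus <- list(f1 = greedy_cluster(f1, 1.0), f2 = greedy_cluster(f2, 1.0))
  labels <- dplyr::bind_rows(f1, f2)
  labels <- labels[!duplicated(labels$record_id), ]
  # k=1: all three species collide somewhere
  expect_equal(multi_marker_species_fraction(clus, labels, 1), 100)
  # k=2: only species a collides in both families
  expect_equal(multi_marker_species_fraction(clus, labels, 2), 100 / 3)
  expect_error(multi_marker_species_fraction(clus, labels, 3),
               "configuration error")
  # k=1 with a single family reduces to pct_species_in_msc
  s <- collision_summary(clus$f1, f1)
  expect_equal(multi_marker_species_fraction(clus["f1"], f1, 1),
               s$pct_species_in_msc)
})

test_that("sequences in msc grow with the planted collision rate", {
  n_msc_seq <- vapply(c(0, 0.3, 0.8), function(rate) {
    cfg <- synthetic_config(n_genera = 4, species_per_genus = 4,
                            genomes_per_species = 2,
                            inter_species_divergence = 0.3,
                            intra_species_divergence = 0,
                            collision_rate = rate, seed = 23)
    g <- generate_synthetic_db(cfg)
    collision_summary(greedy_cluster(g$db$records, 1.0),
                      g$db$records)$n_sequences_in_msc
  }, numeric(1))
  expect_true(all(diff(n_msc_seq) >= 0))
  expect_gt(n_msc_seq[3], n_msc_seq[1])
})

test_that("looser thresholds capture at least as many species on average", {
  cfg <- synthetic_config(n_genera = 4, species_per_genus = 3,
                          genomes_per_species = 3,
                          inter_species_divergence = 0.03,
                          intra_species_divergence = 0.004,
                          collision_rate = 0.2, seed = 29)
  g <- generate_synthetic_db(cfg)
  spec <- subsample_spec(sizes = 24, n_replicates = 6, seed = 3)
  man <- subsample_db(g$db, spec)
  mean_pct <- vapply(c(1.0, 0.95), function(th) {
    pct <- vapply(1:6, function(r) {
      ids <- man$record_id[man$replicate == r]
      recs <- g$db$records[match(ids, g$db$records$record_id), ]
      collision_summary(greedy_cluster(recs, th), g$db$records,
                        threshold = th)$pct_species_in_msc
    }, numeric(1))
    mean(pct)
  }, numeric(1))
  expect_gte(mean_pct[2], mean_pct[1])
})
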