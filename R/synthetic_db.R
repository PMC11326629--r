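#' Configuration for the synthetic marker-gene database generator
#'
#' Describes a bacterial-like community from which marker-gene records are
#' simulated: genera containing a variable number of species, species
#' containing a variable number of genomes, and one or more marker-gene
#' families per genome.  One family may be 16S-like (multi-copy, 1-9 copies
#' per genome); protein-coding-like families are single copy.  Sequences
#' evolve by per-site substitution (no indels): each genus carries one random
#' ancestral gene per family, each species' gene derives from it at
#' `inter_species_divergence`, and each genome copy derives from the species
#' gene at `intra_species_divergence`.  With probability `collision_rate` a
#' species' gene for a family is replaced verbatim by the gene of a
#' previously generated congeneric species, planting an exact interspecies
#' sequence collision whose position is recorded in the ground truth.
#'
#' Count-like arguments (`species_per_genus`, `genomes_per_species`,
#' `copy_number`) accept a distribution spec: a single integer (fixed), a
#' length-2 integer vector (inclusive uniform range; note a pair is always a
#' range, never two per-item values), an integer vector of exactly the
#' required length (per-item values), or a `function(n)` returning `n`
#' integers (for heavily skewed designs such as one dominant species).
#'
#' @param n_genera Number of genera.
#' @param species_per_genus Distribution spec for species per genus.
#' @param genomes_per_species Distribution spec for genomes per species
#'   (drawn over all species of the database in genus-major order).
#' @param n_marker_families Number of marker-gene families.
#' @param copy_number Per-family distribution spec for gene copies per
#'   genome; a list of length `n_marker_families` gives one spec per family.
#' @param gene_length_mean,gene_length_sd Mean and standard deviation (nt) of
#'   the ancestral gene length per family; scalars are recycled.
#' @param inter_species_divergence Expected substitutions per site between a
#'   species' gene and its genus ancestor; scalar or per-family vector.
#' @param divergence_spread Heterogeneity of interspecies divergence: each
#'   species' branch divergence is `inter_species_divergence` times a
#'   uniform draw from `[1 - spread, 1 + spread]` (per species and family).
#'   The default 0 gives every species the same expected divergence; real
#'   genera are heterogeneous — some congener pairs are near-identical
#'   while others are clearly separated — which matters when divergences
#'   sit near a clustering threshold.  The mean divergence is unchanged.
#' @param intra_species_divergence Expected substitutions per site between a
#'   genome's gene copy and its species gene.
#' @param collision_rate Probability that a species' gene for a family is a
#'   verbatim copy of a congener's gene (only possible from the second
#'   species of a genus onwards).
#' @param artifact_rate Probability that a record's length is corrupted to a
#'   quarter (truncation) or four times (tandem-duplication-like elongation)
#'   of the family mean, i.e. well outside the half-to-twice filter band.
#' @param marker_ids Optional family names; defaults to `rrs_16S` for a
#'   multi-copy first family when its copy spec allows >1 copy, else
#'   `markerNN`.
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genera,
                             species_per_genus,
                             genomes_per_species = 1L,
                             n_marker_families = 1L,
                             copy_number = 1L,
                             gene_length_mean = 450,
                             gene_length_sd = 25,
                             inter_species_divergence = 0.1,
                             divergence_spread = 0,
                             intra_species_divergence = 0.005,
                             collision_rate = 0,
                             artifact_rate = 0,
                             marker_ids = NULL,
                             seed = 1L) {
  if (n_genera < 1L) stop("configuration error: need at least one genus")
  if (n_marker_families < 1L)
    stop("configuration error: need at least one marker family")
  stopifnot(collision_rate >= 0, collision_rate <= 1,
            artifact_rate >= 0, artifact_rate <= 1,
            all(intra_species_divergence >= 0),
            all(intra_species_divergence < 1),
            all(inter_species_divergence >= 0),
            all(inter_species_divergence < 1),
            divergence_spread >= 0, divergence_spread < 1,
            all(inter_species_divergence * (1 + divergence_spread) < 1),
            all(gene_length_mean >= 1))
  nf <- as.integer(n_marker_families)
  if (!is.list(copy_number)) copy_number <- rep(list(copy_number), nf)
  if (length(copy_number) != nf)
    stop("configuration error: copy_number must give one spec per family")
  if (is.null(marker_ids)) {
    multi <- vapply(copy_number, function(s)
      is.numeric(s) && max(s) > 1, logical(1))
    marker_ids <- sprintf("marker%02d", seq_len(nf))
    if (nf >= 1 && multi[1]) marker_ids[1] <- "rrs_16S"
  }
  stopifnot(length(marker_ids) == nf, !anyDuplicated(marker_ids))
  cfg <- list(
    n_genera = as.integer(n_genera),
    species_per_genus = species_per_genus,
    genomes_per_species = genomes_per_species,
    n_marker_families = nf,
    copy_number = copy_number,
    gene_length_mean = rep_len(gene_length_mean, nf),
    gene_length_sd = rep_len(gene_length_sd, nf),
    inter_species_divergence = rep_len(inter_species_divergence, nf),
    divergence_spread = divergence_spread,
    intra_species_divergence = intra_species_divergence,
    collision_rate = collision_rate,
    artifact_rate = artifact_rate,
    marker_ids = marker_ids,
    seed = as.integer(seed)
  )
  structure(cfg, class = "synthetic_config")
}

#' Listeria-like study configuration
#'
#' A single deeply sampled genus shaped like the RefSeq *Listeria* holdings:
#' 34 species whose genome counts are heavily skewed towards one dominant
#' species (4,439 of 5,014 genomes, the *L. monocytogenes* pattern), with
#' very low interspecies divergence (0.5% expected substitutions per site,
#' the near-identity regime of congeneric *Listeria* marker genes) so that
#' collisions occur at species-proxy identity thresholds.  By default one ribosomal-protein-like single-copy
#' marker family of mean length 450 nt is generated; `with_16S = TRUE` adds
#' a 16S-like multi-copy family (1-9 copies per genome, mean 1,550 nt).
#'
#' @param n_genomes Total genomes (default 5014); the dominant species holds
#'   the same fraction as in the RefSeq census.
#' @param n_species Number of species in the genus (default 34).
#' @param with_16S Add a 16S-like multi-copy family.
#' @param collision_rate,artifact_rate,seed See [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
listeria_like_config <- function(n_genomes = 5014L, n_species = 34L,
                                 with_16S = FALSE,
                                 collision_rate = 0.1,
                                 artifact_rate = 0.005,
                                 seed = 1L) {
  n_dominant <- round(n_genomes * 4439 / 5014)
  rest <- n_genomes - n_dominant
  base <- rest %/% (n_species - 1L)
  extra <- rest %% (n_species - 1L)
  genome_counts <- c(n_dominant,
                     rep(base + 1L, extra),
                     rep(base, n_species - 1L - extra))
  fams <- if (with_16S) 2L else 1L
  synthetic_config(
    n_genera = 1L,
    species_per_genus = n_species,
    genomes_per_species = genome_counts,
    n_marker_families = fams,
    copy_number = if (with_16S) list(c(1L, 9L), 1L) else list(1L),
    gene_length_mean = if (with_16S) c(1550, 450) else 450,
    gene_length_sd = if (with_16S) c(40, 20) else 20,
    inter_species_divergence = 0.005,
    divergence_spread = 0.8,
    intra_species_divergence = 0.002,
    collision_rate = collision_rate,
    artifact_rate = artifact_rate,
    seed = seed
  )
}

# Resolve a distribution spec into n integer draws (consumes RNG only for
# range or function specs).
draw_counts <- function(spec, n, what) {
  if (is.function(spec)) {
    out <- spec(n)
  } else if (length(spec) == 1L) {
    out <- rep(spec, n)
  } else if (length(spec) == 2L && n != 2L) {
    out <- sample(seq.int(spec[1], spec[2]), n, replace = TRUE)
  } else if (length(spec) == 2L && n == 2L && spec[1] <= spec[2] &&
             isTRUE(attr(spec, "per_item"))) {
    out <- spec
  } else if (length(spec) == 2L && n == 2L) {
    out <- sample(seq.int(spec[1], spec[2]), n, replace = TRUE)
  } else if (length(spec) == n) {
    out <- spec
  } else {
    stop("configuration error: bad distribution spec for ", what)
  }
  out <- as.integer(round(out))
  if (any(out < 1L)) stop("configuration error: ", what, " draws below 1")
  out
}

mutate_seq <- function(chars, p) {
  if (p <= 0) return(chars)
  hit <- which(runif(length(chars)) < p)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    # uniform replacement with one of the three other bases
    shift <- sample.int(3L, length(hit), replace = TRUE)
    idx <- (match(chars[hit], bases) - 1L + shift) %% 4L + 1L
    chars[hit] <- bases[idx]
  }
  chars
}

#' Generate a synthetic marker-gene database with known collision structure
#'
#' Simulates every record of a marker-gene database under
#' [synthetic_config()], together with a ground truth listing every planted
#' verbatim interspecies collision and every planted length artifact.  A
#' single RNG stream seeded from `config$seed` is consumed in a fixed,
#' documented order (structure counts, then per genus: ancestral genes per
#' family, then per species per family: divergence and collision draws, then
#' per genome per family: copy numbers, copy divergence and artifact draws),
#' so identical configs reproduce byte-identical databases.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements
#'   * `db`: a [marker_db()] whose records carry genome id, marker family,
#'     full seven-rank lineage, genus and species labels;
#'   * `truth`: a list with `collisions` (tibble: `species_a` donor,
#'     `species_b` recipient, `marker_id`, `n_planted`), `artifacts`
#'     (tibble of corrupted records), `species` (genome census per species)
#'     and `census` (record count per family).
#' @examples
#' cfg <- synthetic_config(n_genera = 2, species_per_genus = 3,
#'                         genomes_per_species = 2, collision_rate = 0.5,
#'                         seed = 1)
#' g <- generate_synthetic_db(cfg)
#' g$db
#' g$truth$collisions
#' @export
generate_synthetic_db <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  bases <- c("A", "C", "G", "T")
  with_seed(cfg$seed, {
    n_sp <- draw_counts(cfg$species_per_genus, cfg$n_genera,
                        "species_per_genus")
    total_species <- sum(n_sp)
    if (total_species < 1L) stop("configuration error: zero species")
    n_gen <- draw_counts(cfg$genomes_per_species, total_species,
                         "genomes_per_species")

    genome_recs <- vector("list", sum(n_gen))
    genome_cursor <- 0L
    coll <- list(); arts <- list(); sp_rows <- list()
    sp_cursor <- 0L

    for (g in seq_len(cfg$n_genera)) {
      genus_name <- sprintf("Genus%03d", g)
      # ancestral gene per family for this genus
      anc <- vector("list", cfg$n_marker_families)
      for (f in seq_len(cfg$n_marker_families)) {
        len <- max(1L, as.integer(round(rnorm(1, cfg$gene_length_mean[f],
                                              cfg$gene_length_sd[f]))))
        anc[[f]] <- sample(bases, len, replace = TRUE)
      }
      # species genes, with collision planting against earlier congeners
      sp_genes <- vector("list", n_sp[g])
      for (s in seq_len(n_sp[g])) {
        species_name <- sprintf("%s species%03d", genus_name, s)
        genes <- vector("list", cfg$n_marker_families)
        for (f in seq_len(cfg$n_marker_families)) {
          div <- cfg$inter_species_divergence[f]
          if (cfg$divergence_spread > 0)
            div <- div * runif(1, 1 - cfg$divergence_spread,
                               1 + cfg$divergence_spread)
          genes[[f]] <- mutate_seq(anc[[f]], div)
          if (s > 1L && cfg$collision_rate > 0 &&
              runif(1) < cfg$collision_rate) {
            donor <- if (s == 2L) 1L else sample.int(s - 1L, 1L)
            genes[[f]] <- sp_genes[[donor]][[f]]
            coll[[length(coll) + 1L]] <- tibble(
              species_a = sprintf("%s species%03d", genus_name, donor),
              species_b = species_name,
              marker_id = cfg$marker_ids[f])
          }
        }
        sp_genes[[s]] <- genes
      }
      # genomes and gene copies
      for (s in seq_len(n_sp[g])) {
        sp_cursor <- sp_cursor + 1L
        species_name <- sprintf("%s species%03d", genus_name, s)
        ngenome <- n_gen[sp_cursor]
        sp_rows[[sp_cursor]] <- tibble(genus = genus_name,
                                       species = species_name,
                                       n_genomes = ngenome)
        for (k in seq_len(ngenome)) {
          genome <- sprintf("G%03dS%03dN%05d", g, s, k)
          g_rid <- character(0); g_mk <- character(0); g_sq <- character(0)
          for (f in seq_len(cfg$n_marker_families)) {
            ncopy <- draw_counts(cfg$copy_number[[f]], 1L, "copy_number")
            for (cp in seq_len(ncopy)) {
              chars <- mutate_seq(sp_genes[[s]][[f]],
                                  cfg$intra_species_divergence)
              sq <- paste(chars, collapse = "")
              rid <- sprintf("%s|%s|c%d", cfg$marker_ids[f], genome, cp)
              if (cfg$artifact_rate > 0 && runif(1) < cfg$artifact_rate) {
                mean_len <- cfg$gene_length_mean[f]
                if (runif(1) < 0.5) {
                  target <- max(1L, as.integer(round(mean_len / 4)))
                  sq <- substr(strrep(sq, 2L), 1L, target)
                } else {
                  target <- as.integer(round(mean_len * 4))
                  sq <- substr(strrep(sq, ceiling(target / nchar(sq)) + 1L),
                               1L, target)
                }
                arts[[length(arts) + 1L]] <- tibble(
                  record_id = rid, marker_id = cfg$marker_ids[f],
                  planted_length = nchar(sq))
              }
              g_rid <- c(g_rid, rid); g_mk <- c(g_mk, cfg$marker_ids[f])
              g_sq <- c(g_sq, sq)
            }
          }
          genome_cursor <- genome_cursor + 1L
          genome_recs[[genome_cursor]] <- list(
            rid = g_rid, gid = rep(genome, length(g_rid)), mk = g_mk,
            gus = rep(genus_name, length(g_rid)),
            spp = rep(species_name, length(g_rid)), sq = g_sq)
        }
      }
    }

    rec_id <- unlist(lapply(genome_recs, `[[`, "rid"), use.names = FALSE)
    gen_id <- unlist(lapply(genome_recs, `[[`, "gid"), use.names = FALSE)
    mk <- unlist(lapply(genome_recs, `[[`, "mk"), use.names = FALSE)
    gus <- unlist(lapply(genome_recs, `[[`, "gus"), use.names = FALSE)
    spp <- unlist(lapply(genome_recs, `[[`, "spp"), use.names = FALSE)
    seqs <- unlist(lapply(genome_recs, `[[`, "sq"), use.names = FALSE)

    records <- tibble(
      record_id = rec_id,
      genome_id = gen_id,
      marker_id = mk,
      domain = "Bacteria",
      phylum = sprintf("Phylum%02d", (match(gus, sort(unique(gus))) - 1L) %% 6L + 1L),
      class = paste0("Class_", sub("^Genus", "", gus)),
      order = paste0("Order_", sub("^Genus", "", gus)),
      family = paste0(gus, "aceae"),
      genus = gus,
      species = spp,
      sequence = seqs,
      length = nchar(seqs)
    )
    collisions <- if (length(coll)) {
      bind_rows(coll) %>%
        count(.data$species_a, .data$species_b, .data$marker_id,
              name = "n_planted")
    } else {
      tibble(species_a = character(), species_b = character(),
             marker_id = character(), n_planted = integer())
    }
    artifacts <- if (length(arts)) bind_rows(arts) else
      tibble(record_id = character(), marker_id = character(),
             planted_length = integer())
    list(
      db = marker_db(records,
                     provenance = sprintf("synthetic (seed %d)", cfg$seed)),
      truth = list(
        collisions = collisions,
        artifacts = artifacts,
        species = bind_rows(sp_rows),
        census = records %>% count(.data$marker_id, name = "n_records"),
        config = cfg
      )
    )
  })
}

#' Write planted-collision ground truth as TSV
#'
#' @param truth The `truth` element of [generate_synthetic_db()] output.
#' @param path Output TSV path (`species_a`, `species_b`, `family`,
#'   `n_planted`).
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth$collisions
  names(out)[names(out) == "marker_id"] <- "family"
  write_tsv_plain(out, path)
}
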