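#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic metabarcoding study
#' generator. The defaults emulate the sampling design the pipeline is aimed
#' at: three fen-meadow sites, eleven hoverfly species in five genera with a
#' handful of individuals of each species per site, and a plant community of
#' about sixty rbcL-barcoded taxa with largely shared site communities.
#'
#' @param seed Integer seed; all randomness fans out from it through
#'   labelled sub-streams, so results are reproducible and adding one stage
#'   never shifts another stage's draws.
#' @param n_sites,n_families,genera_per_family,species_per_genus Community
#'   dimensions. Plant species count is
#'   `n_families * genera_per_family * species_per_genus`.
#' @param ref_length Reference barcode length in bp.
#' @param between_genus_divergence,within_genus_divergence Expected pairwise
#'   Hamming fractions between reference sequences of different genera and
#'   of congeneric species. Must lie in (0, 0.5) with within < between.
#' @param n_pollinator_species,n_pollinator_genera Hoverfly community size;
#'   species are distributed round-robin across genera.
#' @param individuals_per_species_site Individuals sampled per hoverfly
#'   species per site.
#' @param reads_per_individual Merged reads retained per individual.
#' @param read_error_rate Per-base substitution probability in reads.
#' @param preference_concentration Dirichlet concentration of individual
#'   pollen loads around their species-by-site preference centroid. Lower
#'   values concentrate each individual's load on few plant taxa (more
#'   specialised networks); higher values make individuals track the
#'   centroid tightly.
#' @param genus_effect_size Scale of the genus-level shift of preference
#'   centroids in log-weight space; 0 means pollinator genera share one
#'   expected centroid.
#' @param species_effect_sd Within-genus species-level log-weight spread.
#' @param anemophilous_fraction Fraction of plant families flagged
#'   wind-pollinated; those families are named Poaceae, Cyperaceae and
#'   Juncaceae so downstream entomophilous filters engage.
#' @param anemophilous_background Constant share of every preference
#'   centroid spread uniformly over wind-pollinated taxa at the site,
#'   emulating incidental transport of wind-borne pollen.
#' @param site_overlap Fraction of the plant species pool shared by all
#'   sites; remaining species enter each site community independently with
#'   probability 1/2.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_sites = 3L,
                       n_families = 5L,
                       genera_per_family = 4L,
                       species_per_genus = 3L,
                       ref_length = 500L,
                       between_genus_divergence = 0.08,
                       within_genus_divergence = 0.02,
                       n_pollinator_species = 11L,
                       n_pollinator_genera = 5L,
                       individuals_per_species_site = 4L,
                       reads_per_individual = 200L,
                       read_error_rate = 0.005,
                       preference_concentration = 10,
                       genus_effect_size = 1,
                       species_effect_sd = 0.3,
                       anemophilous_fraction = 0.15,
                       anemophilous_background = 0.01,
                       site_overlap = 0.8) {
  cfg <- list(seed = as.integer(seed), n_sites = as.integer(n_sites),
              n_families = as.integer(n_families),
              genera_per_family = as.integer(genera_per_family),
              species_per_genus = as.integer(species_per_genus),
              ref_length = as.integer(ref_length),
              between_genus_divergence = between_genus_divergence,
              within_genus_divergence = within_genus_divergence,
              n_pollinator_species = as.integer(n_pollinator_species),
              n_pollinator_genera = as.integer(n_pollinator_genera),
              individuals_per_species_site =
                as.integer(individuals_per_species_site),
              reads_per_individual = as.integer(reads_per_individual),
              read_error_rate = read_error_rate,
              preference_concentration = preference_concentration,
              genus_effect_size = genus_effect_size,
              species_effect_sd = species_effect_sd,
              anemophilous_fraction = anemophilous_fraction,
              anemophilous_background = anemophilous_background,
              site_overlap = site_overlap)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_sites", "n_families", "genera_per_family",
              "species_per_genus", "ref_length", "n_pollinator_species",
              "n_pollinator_genera", "individuals_per_species_site")
  for (f in counts) {
    if (!is_count(cfg[[f]]) || cfg[[f]] < 1) {
      stop_pollinet(paste0("sim_config: ", f, " must be a positive count"),
                    "pollinet_bad_config")
    }
  }
  div <- c(cfg$within_genus_divergence, cfg$between_genus_divergence)
  if (any(div <= 0) || any(div >= 0.5)) {
    stop_pollinet("sim_config: divergences must lie in (0, 0.5)",
                  "pollinet_bad_config")
  }
  if (cfg$within_genus_divergence >= cfg$between_genus_divergence) {
    stop_pollinet(
      "sim_config: within_genus_divergence must be < between_genus_divergence",
      "pollinet_bad_config")
  }
  if (cfg$preference_concentration <= 0) {
    stop_pollinet("sim_config: preference_concentration must be > 0",
                  "pollinet_bad_config")
  }
  if (cfg$read_error_rate < 0 || cfg$read_error_rate >= 1) {
    stop_pollinet("sim_config: read_error_rate must lie in [0, 1)",
                  "pollinet_bad_config")
  }
  for (f in c("anemophilous_fraction", "anemophilous_background",
              "site_overlap")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop_pollinet(paste0("sim_config: ", f, " must lie in [0, 1]"),
                    "pollinet_bad_config")
    }
  }
  if (!is_count(abs(cfg$seed))) {
    stop_pollinet("sim_config: seed must be an integer",
                  "pollinet_bad_config")
  }
  invisible(cfg)
}

BASES <- c("A", "C", "G", "T")

mutate_seq <- function(chars, rate) {
  n <- stats::rbinom(1, length(chars), rate)
  if (n == 0) return(chars)
  pos <- sample.int(length(chars), n)
  for (p in pos) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1)
  }
  chars
}

wind_family_names <- function(k) {
  base <- c("Poaceae", "Cyperaceae", "Juncaceae")
  if (k <= 3) return(base[seq_len(k)])
  c(base, paste0("Windfam", sprintf("%02d", seq_len(k - 3))))
}

#' Simulate a reference database with a structured taxonomy
#'
#' Builds equal-length reference barcodes along a family > genus > species
#' hierarchy: each family gets an independent random root, genus ancestors
#' diverge from it at half the between-genus rate, and species diverge from
#' their genus ancestor at half the within-genus rate, so pairwise Hamming
#' fractions approximate the configured divergences. A configurable fraction
#' of families is flagged wind-pollinated and named after the wind-pollinated
#' families (Poaceae, Cyperaceae, Juncaceae) that downstream entomophilous
#' filters exclude.
#'
#' @param config A [sim_config()].
#' @return A `refdb` (see [read_reference()]); its taxonomy carries a
#'   logical `anemophilous` column.
#' @export
simulate_taxonomy_refs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_sp <- config$n_families * config$genera_per_family *
    config$species_per_genus
  if (n_sp < 1) {
    stop_pollinet("degenerate config: zero species", "pollinet_bad_config")
  }
  with_subseed(config$seed, "taxonomy", {
    n_wind <- round(config$anemophilous_fraction * config$n_families)
    wind <- wind_family_names(n_wind)
    fams <- character(config$n_families)
    fams[seq_len(n_wind)] <- wind
    if (n_wind < config$n_families) {
      fams[(n_wind + 1):config$n_families] <-
        sprintf("Family%02d", seq_len(config$n_families - n_wind))
    }
    rows <- list()
    seqs <- character(0)
    g_global <- 0L
    idx <- 0L
    for (f in seq_len(config$n_families)) {
      root <- sample(BASES, config$ref_length, replace = TRUE)
      for (g in seq_len(config$genera_per_family)) {
        g_global <- g_global + 1L
        genus <- sprintf("Genus%03d", g_global)
        tribe <- sprintf("Tribe%02d%s", f, letters[ceiling(g / 2)])
        anc <- mutate_seq(root, config$between_genus_divergence / 2)
        for (s in seq_len(config$species_per_genus)) {
          idx <- idx + 1L
          sp <- paste0(genus, " sp", s)
          chars <- mutate_seq(anc, config$within_genus_divergence / 2)
          ref_id <- sprintf("ref%04d", idx)
          seqs[ref_id] <- paste(chars, collapse = "")
          rows[[idx]] <- tibble(
            ref_id = ref_id, species = sp, genus = genus, tribe = tribe,
            family = fams[f], anemophilous = f <= n_wind)
        }
      }
    }
    new_refdb(seqs, list_rbind(rows))
  })
}

#' Simulate pollen loads, reads and the sampling frame
#'
#' Draws per-site plant communities, genus-structured preference centroids
#' for each pollinator species, individual pollen loads from a Dirichlet
#' around the centroid, and per-individual reads from a multinomial over the
#' load with independent per-base substitution errors. Read headers encode
#' the insect id as `<insect_id>__r<k>`.
#'
#' The preference model: each pollinator genus draws a log-weight vector
#' over plant species scaled by `genus_effect_size`, each species adds an
#' independent perturbation scaled by `species_effect_sd`, and the
#' exponentiated weights restricted to the site community are normalised to
#' the entomophilous centroid. Wind-pollinated taxa at the site receive a
#' constant `anemophilous_background` share spread uniformly.
#'
#' @param config A [sim_config()].
#' @param refdb Output of [simulate_taxonomy_refs()].
#' @return A list with `true_loads` (tibble `insect_id`, `taxon`,
#'   `proportion`), `reads` (tibble `read_id`, `sequence`, `length`),
#'   `insects` (metadata tibble) and `site_plants` (per-site species list).
#' @export
simulate_loads_and_reads <- function(config, refdb) {
  stopifnot(inherits(config, "sim_config"), inherits(refdb, "refdb"))
  if (config$reads_per_individual < 1) {
    stop_pollinet("reads_per_individual must be >= 1", "pollinet_bad_config")
  }
  tax <- refdb$taxonomy
  species_pool <- tax$species
  sites <- sprintf("S%02d", seq_len(config$n_sites))

  communities <- with_subseed(config$seed, "communities", {
    n_shared <- round(length(species_pool) * config$site_overlap)
    shared <- sample(species_pool, n_shared)
    lapply(setNames(sites, sites), function(st) {
      rest <- setdiff(species_pool, shared)
      extra <- rest[stats::runif(length(rest)) < 0.5]
      sort(c(shared, extra))
    })
  })
  site_plants <- list_rbind(imap(communities, function(comm, st) {
    tibble(site = st, plant_species = comm,
           family = tax$family[match(comm, tax$species)])
  }))

  # Pollinator roster: species round-robin over genera.
  genera <- sprintf("Hovergenus%s", LETTERS[seq_len(config$n_pollinator_genera)])
  pg <- genera[((seq_len(config$n_pollinator_species) - 1) %%
                  config$n_pollinator_genera) + 1]
  psp <- paste0(pg, " sp",
                ((seq_len(config$n_pollinator_species) - 1) %/%
                   config$n_pollinator_genera) + 1)

  genus_logw <- lapply(setNames(unique(pg), unique(pg)), function(g) {
    with_subseed(config$seed, paste0("pref_genus_", g),
                 config$genus_effect_size *
                   rnorm(length(species_pool)))
  })
  species_logw <- lapply(setNames(psp, psp), function(sp) {
    with_subseed(config$seed, paste0("pref_species_", sp),
                 config$species_effect_sd * rnorm(length(species_pool)))
  })

  anem <- setNames(tax$anemophilous %||% rep(FALSE, nrow(tax)), tax$species)
  centroid <- function(sp, g, comm) {
    logw <- genus_logw[[g]][match(comm, species_pool)] +
      species_logw[[sp]][match(comm, species_pool)]
    wind <- anem[comm]
    pi <- numeric(length(comm))
    if (all(wind)) {
      pi[] <- 1 / length(comm)
    } else {
      bg <- if (any(wind)) config$anemophilous_background else 0
      w <- exp(logw[!wind])
      pi[!wind] <- (1 - bg) * w / sum(w)
      if (any(wind)) pi[wind] <- bg / sum(wind)
    }
    setNames(pi, comm)
  }

  insects <- list()
  loads <- list()
  read_ids <- list()
  read_seqs <- list()
  ref_of_species <- setNames(refdb$sequences[tax$ref_id], tax$species)
  for (st in sites) {
    comm <- communities[[st]]
    for (k in seq_len(config$n_pollinator_species)) {
      ctr <- centroid(psp[k], pg[k], comm)
      for (i in seq_len(config$individuals_per_species_site)) {
        insect_id <- sprintf("%s_%s_%02d", st, gsub(" ", "-", psp[k]), i)
        insects[[insect_id]] <- tibble(
          insect_id = insect_id, pollinator_species = psp[k],
          genus = pg[k], site = st)
        res <- with_subseed(config$seed, paste0("load_", insect_id), {
          y <- rgamma(length(ctr), shape = config$preference_concentration * ctr)
          if (sum(y) <= 0 || !all(is.finite(y))) {
            y <- as.numeric(stats::rmultinom(1, 1, ctr))
          }
          load <- y / sum(y)
          counts <- as.integer(rmultinom(1, config$reads_per_individual, load))
          sqs <- character(config$reads_per_individual)
          j0 <- 0L
          L <- config$ref_length
          for (j in which(counts > 0)) {
            tmpl <- utf8ToInt(ref_of_species[[comm[j]]])
            for (r in seq_len(counts[j])) {
              s <- tmpl
              ne <- stats::rbinom(1, L, config$read_error_rate)
              if (ne > 0) {
                pos <- sample.int(L, ne)
                for (p in pos) {
                  s[p] <- utf8ToInt(sample(setdiff(BASES, intToUtf8(s[p])), 1))
                }
              }
              j0 <- j0 + 1L
              sqs[j0] <- intToUtf8(s, multiple = FALSE)
            }
          }
          list(load = load, seqs = sqs)
        })
        loads[[insect_id]] <- tibble(insect_id = insect_id, taxon = comm,
                                     proportion = res$load)
        ids <- sprintf("%s__r%03d", insect_id,
                       seq_len(config$reads_per_individual))
        read_ids[[insect_id]] <- ids
        read_seqs[[insect_id]] <- res$seqs
      }
    }
  }
  reads <- tibble(read_id = unlist(read_ids, use.names = FALSE),
                  sequence = unlist(read_seqs, use.names = FALSE))
  reads$length <- nchar(reads$sequence)
  list(true_loads = list_rbind(loads), reads = reads,
       insects = list_rbind(insects), site_plants = site_plants)
}

#' Simulate an alignment hit table
#'
#' Scores every read against every reference by ungapped identity over the
#' aligned prefix and emits, per read, the references whose pseudo-bit-score
#' ranks in the best `top_n`, with ties at the cut retained. The
#' pseudo-bit-score is the stated linear function
#' `max(0, 2 * (matches - mismatches))` of the ungapped comparison, not a
#' Karlin-Altschul score: downstream consensus assignment consumes only the
#' ranking, and a linear score keeps the simulator exactly checkable.
#'
#' @param reads Tibble with `read_id`, `sequence` (e.g. from
#'   [simulate_loads_and_reads()] or [read_reads()]).
#' @param refdb Reference database; sequences must share one length.
#' @param top_n Number of best-scoring references reported per read. The
#'   default 1 (the maximal-scoring reference set, with ties) matches the
#'   discriminative content of a deep search against a multi-accession
#'   library when, as here, the synthetic library holds a single accession
#'   per species: deeper lists on such a library dilute the downstream
#'   consensus below the genus threshold as an artefact of library
#'   composition rather than of the reads.
#' @return A hit tibble in the layout of [read_hit_table()]. Empty read sets
#'   yield an empty table.
#' @export
simulate_hit_table <- function(reads, refdb, top_n = 1L) {
  stopifnot(inherits(refdb, "refdb"))
  cols <- c("query_id", "subject_id", "percent_identity", "align_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "e_value", "bit_score")
  if (nrow(reads) == 0) {
    out <- as_tibble(setNames(
      c(list(character(), character()), rep(list(numeric()), 10)), cols))
    out$align_length <- integer()
    return(out)
  }
  rl <- unique(nchar(refdb$sequences))
  if (length(rl) != 1) {
    stop_pollinet("references must share one length", "pollinet_bad_input")
  }
  L <- min(rl, min(nchar(reads$sequence)))

  onehot <- function(sqs, L) {
    n <- length(sqs)
    code <- matrix(0L, n, L)
    for (i in seq_len(n)) {
      v <- utf8ToInt(substr(sqs[i], 1, L))
      code[i, ] <- match(v, utf8ToInt("ACGT"), nomatch = 0L)
    }
    oh <- matrix(0, n, 4L * L)
    for (b in 1:4) {
      sel <- code == b
      oh[, ((b - 1L) * L + 1L):(b * L)][sel] <- 1
    }
    oh
  }
  ref_oh <- onehot(unname(refdb$sequences), L)
  read_oh <- onehot(reads$sequence, L)
  matches <- read_oh %*% t(ref_oh)  # reads x refs

  ref_ids <- names(refdb$sequences)
  bit <- pmax(2 * (2 * matches - L), 0)          # 2 * (matches - mismatches)
  cut <- apply(bit, 1, function(b) {
    -sort(-b, partial = min(top_n, length(b)))[min(top_n, length(b))]
  })
  keep <- which(bit >= cut, arr.ind = TRUE)       # row = read, col = ref
  keep <- keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
  mi <- matches[keep]
  bits <- bit[keep]
  out <- tibble(
    query_id = reads$read_id[keep[, 1]],
    subject_id = ref_ids[keep[, 2]],
    percent_identity = 100 * mi / L,
    align_length = as.integer(L),
    mismatches = as.integer(L - mi),
    gap_opens = 0L, q_start = 1L, q_end = as.integer(L),
    s_start = 1L, s_end = as.integer(L),
    e_value = 2^(-(bits - 2 * L) / 10),
    bit_score = bits)
  arrange(out, .data$query_id)
}

#' Run the whole simulator
#'
#' Convenience wrapper: reference database, sampling frame, loads, reads and
#' hit table in one deterministic call.
#'
#' @param config A [sim_config()].
#' @param top_n Hits reported per read (see [simulate_hit_table()]).
#' @return A list with `config`, `refdb`, `true_loads`, `reads`, `insects`,
#'   `site_plants`, `hits`.
#' @export
simulate_pollen_study <- function(config = sim_config(), top_n = 1L) {
  refdb <- simulate_taxonomy_refs(config)
  lr <- simulate_loads_and_reads(config, refdb)
  hits <- simulate_hit_table(lr$reads, refdb, top_n = top_n)
  c(list(config = config, refdb = refdb, hits = hits), lr)
}

#' Write a simulated study to disk
#'
#' Writes refs.fasta, taxonomy.csv, reads.fasta, hits.tsv, insects.csv,
#' sites.csv and true_loads.csv under `dir`.
#'
#' @param sim Output of [simulate_pollen_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(refs = file.path(dir, "refs.fasta"),
             taxonomy = file.path(dir, "taxonomy.csv"),
             reads = file.path(dir, "reads.fasta"),
             hits = file.path(dir, "hits.tsv"),
             insects = file.path(dir, "insects.csv"),
             sites = file.path(dir, "sites.csv"),
             true_loads = file.path(dir, "true_loads.csv"))
  write_fasta(sim$refdb$sequences, paths["refs"])
  utils::write.csv(sim$refdb$taxonomy, paths["taxonomy"], row.names = FALSE)
  write_fasta(setNames(sim$reads$sequence, sim$reads$read_id),
              paths["reads"])
  write_hit_table(sim$hits, paths["hits"])
  utils::write.csv(sim$insects, paths["insects"], row.names = FALSE)
  utils::write.csv(sim$site_plants, paths["sites"], row.names = FALSE)
  utils::write.csv(sim$true_loads, paths["true_loads"], row.names = FALSE)
  invisible(paths)
}
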