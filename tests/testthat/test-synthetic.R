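test_that("taxonomy simulation yields the configured record count and is deterministic", {
  cfg <- tiny_sim_config(seed = 5, n_families = 2, genera_per_family = 2,
                         species_per_genus = 2)
  db <- simulate_taxonomy_refs(cfg)
  expect_equal(length(db$sequences), 8)
  expect_equal(nrow(db$taxonomy), 8)
  db2 <- simulate_taxonomy_refs(cfg)
  expect_identical(db$sequences, db2$sequences)
  expect_identical(db$taxonomy, db2$taxonomy)
  # invalid configs refuse to build
  expect_error(sim_config(within_genus_divergence = 0.1,
                          between_genus_divergence = 0.05),
               class = "pollinet_bad_config")
  expect_error(sim_config(preference_concentration = 0),
               class = "pollinet_bad_config")
})

test_that("within-genus divergence is below between-genus divergence", {
  hamming <- function(a, b) {
    mean(utf8ToInt(a) != utf8ToInt(b))
  }
  within <- c()
  between <- c()
  for (seed in 1:20) {
    cfg <- tiny_sim_config(seed = seed, ref_length = 200L)
    db <- simulate_taxonomy_refs(cfg)
    tax <- db$taxonomy
    sq <- db$sequences[tax$ref_id]
    n <- length(sq)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      h <- hamming(sq[i], sq[j])
      if (tax$genus[i] == tax$genus[j]) within <- c(within, h)
      else between <- c(between, h)
    }
  }
  expect_lt(mean(within), mean(between))
  # and the means land near the configured rates
  expect_equal(mean(within), 0.02, tolerance = 0.5)
  expect_equal(mean(between), 0.08, tolerance = 0.5)
})

test_that("each insect gets exactly reads_per_individual reads encoding its id", {
  cfg <- tiny_sim_config(seed = 2)
  db <- simulate_taxonomy_refs(cfg)
  lr <- simulate_loads_and_reads(cfg, db)
  per <- table(sub("__.*$", "", lr$reads$read_id))
  expect_true(all(per == cfg$reads_per_individual))
  expect_setequal(names(per), lr$insects$insect_id)
  expect_equal(nrow(lr$insects),
               cfg$n_sites * cfg$n_pollinator_species *
                 cfg$individuals_per_species_site)
  # loads are simplexes supported on the insect's site community
  sums <- tapply(lr$true_loads$proportion, lr$true_loads$insect_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  comm <- split(lr$site_plants$plant_species, lr$site_plants$site)
  ins_site <- setNames(lr$insects$site, lr$insects$insect_id)
  by_insect <- split(lr$true_loads$taxon, lr$true_loads$insect_id)
  for (id in names(by_insect)) {
    expect_true(all(by_insect[[id]] %in% comm[[ins_site[[id]]]]))
  }
  expect_error(
    simulate_loads_and_reads(tiny_sim_config(reads_per_individual = 0), db),
    class = "pollinet_bad_config")
})

test_that("load variance shrinks as the Dirichlet concentration grows", {
  spread <- function(conc) {
    devs <- c()
    for (seed in 1:10) {
      cfg <- tiny_sim_config(seed = seed, preference_concentration = conc,
                             reads_per_individual = 1L,
                             n_pollinator_species = 2L,
                             n_pollinator_genera = 1L,
                             individuals_per_species_site = 6L,
                             n_sites = 1L)
      db <- simulate_taxonomy_refs(cfg)
      lr <- simulate_loads_and_reads(cfg, db)
      wide <- tidyr::pivot_wider(lr$true_loads, names_from = taxon,
                                 values_from = proportion,
                                 values_fill = 0)
      meta <- dplyr::left_join(wide, lr$insects, by = "insect_id")
      for (sp in unique(meta$pollinator_species)) {
        sub <- as.matrix(meta[meta$pollinator_species == sp,
                              setdiff(names(wide), "insect_id")])
        devs <- c(devs, mean(apply(sub, 2, stats::var)))
      }
    }
    mean(devs)
  }
  expect_lt(spread(1e4), spread(1) / 10)
})

test_that("zero effect sizes collapse all preference centroids to one", {
  # at huge concentration every individual's load sits on the centroid, so
  # equal loads across pollinator genera demonstrate equal centroids
  cfg <- tiny_sim_config(seed = 3, genus_effect_size = 0,
                         species_effect_sd = 0,
                         preference_concentration = 1e7,
                         anemophilous_fraction = 0, n_sites = 1L,
                         reads_per_individual = 1L)
  db <- simulate_taxonomy_refs(cfg)
  lr <- simulate_loads_and_reads(cfg, db)
  wide <- tidyr::pivot_wider(lr$true_loads, names_from = taxon,
                             values_from = proportion, values_fill = 0)
  m <- as.matrix(wide[, -1])
  expect_lt(max(apply(m, 2, stats::sd)), 1e-3)
  # expected centroid is uniform over the site community
  expect_equal(unname(colMeans(m)), rep(1 / ncol(m), ncol(m)),
               tolerance = 1e-2)
})

test_that("error-free reads from a one-taxon community copy the reference", {
  cfg1 <- tiny_sim_config(seed = 4, n_families = 1, genera_per_family = 1,
                          species_per_genus = 1, read_error_rate = 0,
                          site_overlap = 1, anemophilous_fraction = 0)
  db1 <- simulate_taxonomy_refs(cfg1)
  lr1 <- simulate_loads_and_reads(cfg1, db1)
  expect_true(all(lr1$reads$sequence == db1$sequences[[1]]))
})

test_that("pseudo-bit-score follows the stated linear formula", {
  cfg <- tiny_sim_config(seed = 9, n_families = 1, genera_per_family = 2,
                         species_per_genus = 2, ref_length = 500L)
  db <- simulate_taxonomy_refs(cfg)
  ref <- db$sequences[[1]]
  # plant 10 mismatches into a copy of reference 1
  chars <- strsplit(ref, "")[[1]]
  pos <- seq(5, 500, length.out = 10)
  for (p in pos) {
    chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  }
  reads <- tibble::tibble(read_id = c("v__r1", "m__r1"),
                          sequence = c(ref, paste(chars, collapse = "")))
  hits <- simulate_hit_table(reads, db, top_n = 4)
  verb <- hits[hits$query_id == "v__r1", ]
  expect_equal(verb$bit_score[which.max(verb$bit_score)], 2 * 500)
  expect_equal(verb$subject_id[which.max(verb$bit_score)], names(db$sequences)[1])
  mut <- hits[hits$query_id == "m__r1", ]
  best <- mut[which.max(mut$bit_score), ]
  expect_equal(best$bit_score, 2 * (490 - 10))
  expect_equal(best$mismatches, 10L)
  expect_equal(best$percent_identity, 100 * 490 / 500)
})

test_that("equidistant references are both reported at equal score", {
  db <- pollinet:::new_refdb(
    c(rA = "AAAAAAAAAA", rB = "CCCCAAAAAA"),
    tibble::tibble(ref_id = c("rA", "rB"),
                   species = c("X a", "X b"), genus = "X",
                   tribe = NA_character_, family = "F"))
  # read differs from rA and rB by the same 2 positions
  reads <- tibble::tibble(read_id = "q__r1", sequence = "CCAAAAAAAA")
  hits <- simulate_hit_table(reads, db, top_n = 1)
  expect_equal(nrow(hits), 2)
  expect_equal(length(unique(hits$bit_score)), 1)
  # empty read set -> empty table
  empty <- simulate_hit_table(reads[0, ], db)
  expect_equal(nrow(empty), 0)
})

test_that("the full simulator is deterministic under a fixed seed", {
  cfg <- tiny_sim_config(seed = 42, reads_per_individual = 10L)
  s1 <- simulate_pollen_study(cfg)
  s2 <- simulate_pollen_study(cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$hits, s2$hits)
  expect_identical(s1$true_loads, s2$true_loads)
  dir <- withr::local_tempdir()
  p1 <- write_simulation(s1, file.path(dir, "a"))
  p2 <- write_simulation(s2, file.path(dir, "b"))
  expect_identical(readLines(p1[["refs"]]), readLines(p2[["refs"]]))
  expect_identical(readLines(p1[["reads"]]), readLines(p2[["reads"]]))
})
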