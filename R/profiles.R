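#' Convert pollen counts to percentages
#'
#' Row-normalises each insect's identified (non-`unknown`) read counts to
#' percentages, controlling for between-sample differences in amplification
#' depth. Insects with zero identified reads are excluded with a warning.
#'
#' @param counts Long count tibble from [tally_pollen()].
#' @return Long tibble `insect_id`, `taxon`, `rank`, `percent`; each
#'   retained insect's percentages sum to 100.
#' @export
to_percent <- function(counts) {
  known <- filter(counts, .data$rank != "unknown")
  empty <- setdiff(unique(counts$insect_id), unique(known$insect_id))
  if (length(empty) > 0) {
    warn(paste0("excluding insect(s) with no identified reads: ",
                paste(head(empty, 5), collapse = ", ")))
  }
  known |>
    group_by(.data$insect_id) |>
    mutate(percent = 100 * .data$count / sum(.data$count)) |>
    ungroup() |>
    select("insect_id", "taxon", "rank", "percent")
}

#' Convert pollen counts to presence/absence
#'
#' A taxon is present in an insect when its read count reaches
#' `presence_min_reads`. The `unknown` tally never yields a presence, and
#' taxa present in no insect are dropped.
#'
#' @param counts Long count tibble from [tally_pollen()].
#' @param presence_min_reads Detection threshold in reads (default 1; no
#'   threshold beyond detection).
#' @return Long tibble `insect_id`, `taxon`, `rank` of present pairs only.
#' @export
to_presence_absence <- function(counts, presence_min_reads = 1L) {
  counts |>
    filter(.data$rank != "unknown",
           .data$count >= presence_min_reads) |>
    select("insect_id", "taxon", "rank") |>
    arrange(.data$insect_id, .data$taxon)
}

#' Presence/absence input for Jaccard comparisons
#'
#' The comparison suite uses presence/absence, which overweights rare taxa;
#' this filter therefore drops taxa identified *above* genus level (family,
#' tribe or uncurated `various`) whose study-wide read total is strictly
#' below `threshold` of all identified reads, then drops `unknown`, then
#' converts to presence/absence. Species- and genus-rank taxa are never
#' dropped regardless of abundance, and an above-genus taxon at exactly the
#' threshold is retained.
#'
#' @param counts Long count tibble from [tally_pollen()].
#' @param threshold Fraction of the grand total of identified reads
#'   (default 0.01).
#' @param presence_min_reads Detection threshold passed on to
#'   [to_presence_absence()].
#' @return Long presence tibble as from [to_presence_absence()].
#' @export
jaccard_input_filter <- function(counts, threshold = 0.01,
                                 presence_min_reads = 1L) {
  known <- filter(counts, .data$rank != "unknown")
  grand <- sum(known$count)
  totals <- known |>
    group_by(.data$taxon, .data$rank) |>
    summarise(total = sum(.data$count), .groups = "drop")
  drop <- totals |>
    filter(.data$rank %in% c("family", "tribe", "various"),
           .data$total < threshold * grand)
  known |>
    anti_join(drop, by = c("taxon", "rank")) |>
    to_presence_absence(presence_min_reads = presence_min_reads)
}

#' Entomophilous community coverage
#'
#' How much of a site's insect-pollinated flora shows up in the pollen
#' record. The entomophilous sub-list is the site's plant list minus
#' grasses (Poaceae), sedges (Cyperaceae) and rushes (Juncaceae). A
#' species-rank pollen taxon detects its species when listed; a pollen
#' taxon above species rank (genus, family or tribe) is assumed to come
#' from a single plant species, so it detects at most one matched sub-list
#' species no matter how many the site holds, and detects none when the
#' site holds none.
#'
#' @param site_plants Site plant list tibble (`site`, `plant_species`,
#'   `family`).
#' @param pollen_taxa Tibble of detected pollen taxa at the site: columns
#'   `taxon`, `rank`.
#' @param site Site label; must occur in `site_plants`.
#' @param taxonomy Optional taxonomy tibble used to resolve tribe-rank
#'   pollen taxa to genera; without it a tribe taxon matches no species.
#' @return One-row tibble `site`, `n_entomophilous`, `n_detected`,
#'   `fraction`.
#' @export
entomophilous_coverage <- function(site_plants, pollen_taxa, site,
                                   taxonomy = NULL) {
  sp <- filter(site_plants, .data$site == !!site)
  if (nrow(sp) == 0) {
    stop_pollinet(paste0("site not in plant list: ", site),
                  "pollinet_bad_input")
  }
  wind <- c("Poaceae", "Cyperaceae", "Juncaceae")
  ento <- filter(sp, !.data$family %in% wind)
  species <- ento$plant_species
  genus_of <- sub("\\s.*$", "", species)
  family_of <- ento$family
  detected <- character(0)
  for (i in seq_len(nrow(pollen_taxa))) {
    tx <- pollen_taxa$taxon[i]
    rk <- pollen_taxa$rank[i]
    hit <- switch(
      rk,
      species = species[species == tx],
      genus = species[genus_of == tx],
      family = species[family_of == tx],
      tribe = {
        if (is.null(taxonomy)) character(0) else {
          gen <- unique(taxonomy$genus[taxonomy$tribe %in% tx])
          species[genus_of %in% gen]
        }
      },
      character(0))
    if (length(hit) > 0) {
      # A supra-specific taxon stands for one plant species.
      detected <- union(detected, if (rk == "species") hit else hit[1])
    }
  }
  n_ento <- length(species)
  n_det <- length(detected)
  tibble(site = site, n_entomophilous = n_ento, n_detected = n_det,
         fraction = if (n_ento > 0) n_det / n_ento else NA_real_)
}
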