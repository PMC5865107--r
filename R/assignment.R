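#' Assignment rule parameters
#'
#' The consensus classification rule applied to each read's alignment hits:
#' keep the hits in the `top_k` highest distinct bit-score values (all ties
#' retained), assign to a species when every retained hit agrees on one,
#' otherwise to a genus when at least `genus_fraction` of the retained hits
#' share one genus, otherwise to `various`. Reads of `min_length` bp or
#' shorter are excluded before assignment (strictly greater-than filter).
#'
#' @param top_k Number of distinct top bit-score values retained per read.
#' @param genus_fraction Minimum fraction of retained hits that must share a
#'   genus for a genus-level call; in (0, 1].
#' @param min_length Length filter threshold in bp; reads must exceed it.
#' @param score_weighted If `TRUE`, the genus fraction is bit-score-weighted
#'   instead of hit-count-weighted. Off by default: the plain hit-count
#'   reading is the simplest one.
#' @return A list of class `assignment_rule`.
#' @export
assignment_rule <- function(top_k = 20L, genus_fraction = 0.60,
                            min_length = 450L, score_weighted = FALSE) {
  if (!is_count(top_k) || top_k < 1) {
    stop_pollinet("top_k must be a count >= 1", "pollinet_bad_config")
  }
  if (genus_fraction <= 0 || genus_fraction > 1) {
    stop_pollinet("genus_fraction must lie in (0, 1]", "pollinet_bad_config")
  }
  if (!is_count(min_length)) {
    stop_pollinet("min_length must be a non-negative count",
                  "pollinet_bad_config")
  }
  structure(list(top_k = as.integer(top_k), genus_fraction = genus_fraction,
                 min_length = as.integer(min_length),
                 score_weighted = isTRUE(score_weighted)),
            class = "assignment_rule")
}

#' Length-filter reads
#'
#' Retains reads strictly longer than the threshold (a 451 bp read passes a
#' 450 bp threshold; a 450 bp read does not). The number removed is
#' reported via a message.
#'
#' @param reads Tibble with `read_id` and `sequence` and/or `length`.
#' @param min_length Exclusive lower bound in bp.
#' @return The retained rows of `reads`.
#' @export
length_filter <- function(reads, min_length = 450L) {
  len <- reads[["length"]] %||% nchar(reads$sequence)
  keep <- len > min_length
  removed <- sum(!keep)
  inform(sprintf("length_filter: removed %d of %d read(s) at <= %d bp",
                 removed, length(keep), as.integer(min_length)))
  reads[keep, , drop = FALSE]
}

#' Retain the top-scoring hits per read
#'
#' For each query, keeps every hit whose bit score is among the `top_k`
#' highest *distinct* bit-score values for that query; ties at any retained
#' level are all kept, and queries with fewer than `top_k` distinct values
#' keep all their hits. Reading the top-k rule over distinct score values
#' (rather than the first k file rows) makes the result deterministic and
#' independent of hit order.
#'
#' @param hits Hit tibble (see [read_hit_table()]).
#' @param rule An [assignment_rule()].
#' @return The retained hit rows.
#' @export
select_top_hits <- function(hits, rule = assignment_rule()) {
  if (nrow(hits) == 0) return(hits)
  hits |>
    group_by(.data$query_id) |>
    filter({
      lv <- sort(unique(.data$bit_score), decreasing = TRUE)
      .data$bit_score >= lv[min(rule$top_k, length(lv))]
    }) |>
    ungroup()
}

#' Consensus taxonomic assignment
#'
#' Applies the consensus rule to each query's retained hits: a unanimous
#' species wins; otherwise a genus accounting for at least
#' `rule$genus_fraction` of the retained hits wins; otherwise the read is
#' `various`. Queries listed in `query_ids` but absent from `hits` are
#' `unknown` (zero hits). The decision is invariant to hit order. Each
#' assignment also records the sorted set of hit families
#' (`family_signature`), the key the curation tier matches on.
#'
#' @param hits Retained hits, e.g. from [select_top_hits()].
#' @param taxonomy Taxonomy tibble; every `subject_id` must resolve, else a
#'   hard error.
#' @param rule An [assignment_rule()].
#' @param query_ids Optional character vector of all queries that entered
#'   the search (post length filter); members without hits become `unknown`.
#' @return Tibble with `query_id`, `label`, `rank` (species/genus/various/
#'   unknown), `n_hits_considered`, `family_signature`.
#' @export
consensus_assign <- function(hits, taxonomy, rule = assignment_rule(),
                             query_ids = NULL) {
  missing <- setdiff(unique(hits$subject_id), taxonomy$ref_id)
  if (length(missing) > 0) {
    stop_pollinet(
      paste0("hit subject_id(s) absent from taxonomy: ",
             paste(head(missing, 5), collapse = ", ")),
      "pollinet_missing_taxonomy")
  }
  idx <- match(hits$subject_id, taxonomy$ref_id)
  h <- tibble(query_id = hits$query_id,
              species = taxonomy$species[idx],
              genus = taxonomy$genus[idx],
              family = taxonomy$family[idx],
              w = if (rule$score_weighted) hits$bit_score else
                rep(1, nrow(hits)))
  assigned <- h |>
    group_by(.data$query_id) |>
    summarise(out = list(consensus_one(.data$species, .data$genus,
                                       .data$family, .data$w, rule)),
              .groups = "drop") |>
    tidyr::unnest_wider("out")
  if (!is.null(query_ids)) {
    missing_q <- setdiff(query_ids, assigned$query_id)
    if (length(missing_q) > 0) {
      assigned <- bind_rows(assigned, tibble(
        query_id = missing_q, label = "unknown", rank = "unknown",
        n_hits_considered = 0L, family_signature = ""))
    }
  }
  arrange(assigned, .data$query_id)
}

consensus_one <- function(species, genus, family, w, rule) {
  sig <- paste(sort(unique(family)), collapse = "|")
  n <- length(species)
  sp <- unique(species)
  if (length(sp) == 1 && !is.na(sp)) {
    return(list(label = sp, rank = "species", n_hits_considered = n,
                family_signature = sig))
  }
  gw <- tapply(w, genus, sum)
  gw <- gw[!is.na(names(gw))]
  if (length(gw) > 0) {
    frac <- gw / sum(w)
    qual <- names(frac)[frac >= rule$genus_fraction]
    # At thresholds > 0.5 at most one genus can qualify; at configured
    # thresholds <= 0.5 a tie between top qualifying genera falls to various.
    if (length(qual) >= 1) {
      win <- qual[frac[qual] == max(frac[qual])]
      if (length(win) == 1) {
        return(list(label = win, rank = "genus", n_hits_considered = n,
                    family_signature = sig))
      }
    }
  }
  list(label = "various", rank = "various", n_hits_considered = n,
       family_signature = sig)
}

#' Apply a curation map to consensus assignments
#'
#' Resolves `various` assignments to family or tribe level where an expert
#' rule applies, emulating the manual verification tier of metabarcoding
#' pipelines. Rules (see [read_curation()]) are tried in order; `query`
#' rules match an explicit read id, `signature` rules match the read's
#' family signature. `various` reads with no matching rule become
#' `unknown`. Non-`various` assignments pass through untouched. Every remap
#' is recorded in an audit log attached as the `"audit"` attribute.
#'
#' @param assignments Output of [consensus_assign()].
#' @param curation Curation rules tibble (may have zero rows).
#' @param taxonomy Taxonomy tibble used to validate family/tribe labels.
#' @return The curated assignments; former `various` rows now carry rank
#'   `family`, `tribe` or `unknown`.
#' @export
apply_curation <- function(assignments, curation, taxonomy) {
  bad <- curation$new_rank == "family" &
    !curation$new_label %in% taxonomy$family
  if (any(bad)) {
    stop_pollinet(
      paste0("curation rule names unknown family: ",
             paste(unique(curation$new_label[bad]), collapse = ", ")),
      "pollinet_bad_value")
  }
  bad <- curation$new_rank == "tribe" &
    !curation$new_label %in% taxonomy$tribe
  if (any(bad)) {
    stop_pollinet(
      paste0("curation rule names unknown tribe: ",
             paste(unique(curation$new_label[bad]), collapse = ", ")),
      "pollinet_bad_value")
  }
  out <- assignments
  audit <- list()
  various <- which(out$rank == "various")
  for (i in various) {
    hit <- NULL
    if (nrow(curation) > 0) {
      for (r in seq_len(nrow(curation))) {
        ok <- switch(curation$rule_type[r],
                     query = curation$key[r] == out$query_id[i],
                     signature = curation$key[r] == out$family_signature[i])
        if (isTRUE(ok)) { hit <- r; break }
      }
    }
    if (is.null(hit)) {
      new_rank <- "unknown"; new_label <- "unknown"; rule_id <- NA_integer_
    } else {
      new_rank <- curation$new_rank[hit]
      new_label <- if (new_rank == "unknown") "unknown" else
        curation$new_label[hit]
      rule_id <- hit
    }
    audit[[length(audit) + 1]] <- tibble(
      query_id = out$query_id[i], old_rank = "various",
      new_rank = new_rank, new_label = new_label, rule = rule_id)
    out$rank[i] <- new_rank
    out$label[i] <- new_label
  }
  attr(out, "audit") <- if (length(audit)) list_rbind(audit) else
    tibble(query_id = character(), old_rank = character(),
           new_rank = character(), new_label = character(),
           rule = integer())
  out
}

#' Tally assignments into per-insect pollen counts
#'
#' Maps each read to its insect (by default by splitting the read id at
#' `"__"`, the simulator's convention; supply `read_insect` for other
#' header schemes) and counts reads per insect and rank-qualified taxon.
#' Unassignable reads are tallied in a dedicated `unknown` taxon so row sums
#' equal the number of length-passing reads per insect.
#'
#' @param assignments Curated or raw consensus assignments.
#' @param insects Insect metadata tibble; every parsed insect id must be
#'   present, else an error listing examples.
#' @param read_insect Optional named character vector mapping `query_id` to
#'   `insect_id`; overrides header parsing.
#' @return Long tibble `insect_id`, `taxon`, `rank`, `count` (count > 0
#'   rows only), ordered by insect then taxon.
#' @export
tally_pollen <- function(assignments, insects, read_insect = NULL) {
  if (is.null(read_insect)) {
    ids <- sub("__.*$", "", assignments$query_id)
  } else {
    ids <- unname(read_insect[assignments$query_id])
    if (anyNA(ids)) {
      stop_pollinet(
        paste0("read(s) missing from read_insect map: ",
               paste(head(assignments$query_id[is.na(ids)], 5),
                     collapse = ", ")),
        "pollinet_orphan_read")
    }
  }
  orphan <- !ids %in% insects$insect_id
  if (any(orphan)) {
    stop_pollinet(
      paste0("read(s) map to unknown insect id(s), e.g.: ",
             paste(head(unique(ids[orphan]), 5), collapse = ", ")),
      "pollinet_orphan_read")
  }
  tibble(insect_id = ids, taxon = assignments$label,
         rank = assignments$rank) |>
    count(.data$insect_id, .data$taxon, .data$rank, name = "count") |>
    arrange(.data$insect_id, .data$taxon)
}
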