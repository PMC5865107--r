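#' Load a pipeline configuration
#'
#' Reads a YAML run configuration, applies the standard defaults (top 20
#' distinct bit scores, 60% genus fraction, 450 bp length filter, 9999
#' permutations, alpha 0.05) and rejects unknown keys loudly. A run either
#' simulates its inputs (`simulate:` block, merged into [sim_config()]) or
#' reads them from the `paths:` block.
#'
#' @param yaml_path Path to the YAML file.
#' @return A validated list of class `pipeline_config`.
#' @export
load_config <- function(yaml_path) {
  raw <- yaml::read_yaml(yaml_path)
  known <- c("seed", "out_dir", "simulate", "paths", "rule", "hit_top_n",
             "presence_min_reads", "rare_above_genus_threshold", "n_perm",
             "alpha", "log_level")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop_pollinet(paste0("unknown config key(s): ",
                         paste(unknown, collapse = ", ")),
                  "pollinet_bad_config")
  }
  rule_keys <- c("top_k", "genus_fraction", "min_length", "score_weighted")
  bad <- setdiff(names(raw$rule %||% list()), rule_keys)
  if (length(bad) > 0) {
    stop_pollinet(paste0("unknown rule key(s): ",
                         paste(bad, collapse = ", ")),
                  "pollinet_bad_config")
  }
  if (is.null(raw$out_dir)) {
    stop_pollinet("config must name out_dir", "pollinet_bad_config")
  }
  cfg <- list(
    seed = as.integer(raw$seed %||% 1L),
    out_dir = raw$out_dir,
    simulate = raw$simulate,
    paths = raw$paths,
    rule = do.call(assignment_rule, raw$rule %||% list()),
    presence_min_reads = as.integer(raw$presence_min_reads %||% 1L),
    rare_above_genus_threshold = raw$rare_above_genus_threshold %||% 0.01,
    hit_top_n = as.integer(raw$hit_top_n %||% 1L),
    n_perm = as.integer(raw$n_perm %||% 9999L),
    alpha = raw$alpha %||% 0.05,
    log_level = raw$log_level %||% "info")
  if (is.null(cfg$simulate) && is.null(cfg$paths)) {
    stop_pollinet("config must provide either a simulate block or paths",
                  "pollinet_bad_config")
  }
  if (!is.null(cfg$paths)) {
    need <- c("hits", "taxonomy", "reads", "insects", "sites")
    missing <- setdiff(need, names(cfg$paths))
    if (length(missing) > 0) {
      stop_pollinet(paste0("config paths block is missing: ",
                           paste(missing, collapse = ", ")),
                    "pollinet_bad_config")
    }
    if (anyDuplicated(unlist(cfg$paths))) {
      stop_pollinet("config paths must be distinct", "pollinet_bad_config")
    }
  }
  structure(cfg, class = "pipeline_config")
}

pipe_log <- function(cfg, stage, msg) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[pollinet:%s] %s", stage, msg))
}

#' Run the full pipeline
#'
#' Orchestrates simulate (or load) -> assign -> profiles -> networks ->
#' stats, writing every intermediate under `out_dir` and returning (and
#' writing) a run manifest that records seeds, input digests, per-stage
#' record counts and result paths. Reruns with an identical configuration
#' produce identical manifest digests. A failure in any stage aborts with
#' the stage name in the error.
#'
#' @param config A [load_config()] result (or the path to a YAML file).
#' @return The manifest, invisibly; written as `manifest.json` in
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "pollinet",
                   version = as.character(utils::packageVersion("pollinet")),
                   seed = config$seed, stages = list())
  stage <- function(name, code) {
    pipe_log(config, name, "start")
    tryCatch(code, error = function(e) {
      stop_pollinet(paste0("stage '", name, "' failed: ",
                           conditionMessage(e)),
                    "pollinet_stage_error")
    })
  }

  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      sc <- do.call(sim_config,
                    modifyList(list(seed = config$seed),
                               config$simulate))
      s <- simulate_pollen_study(sc, top_n = config$hit_top_n)
      write_simulation(s, file.path(config$out_dir, "sim"))
      s
    })
    refdb <- sim$refdb
    reads <- sim$reads
    hits <- sim$hits
    insects <- sim$insects
    site_plants <- sim$site_plants
    curation <- empty_curation()
    manifest$stages$simulate <- list(
      n_reads = nrow(reads), n_refs = length(refdb$sequences),
      n_insects = nrow(insects),
      digest = content_digest(c(reads$sequence, refdb$sequences)))
  } else {
    p <- config$paths
    refdb <- stage("load", read_reference(p$refs, p$taxonomy))
    reads <- stage("load", read_reads(p$reads))
    hits <- stage("load", read_hit_table(p$hits))
    insects <- stage("load", read_insects(p$insects))
    site_plants <- stage("load", read_site_plants(p$sites))
    curation <- if (is.null(p$curation)) empty_curation() else
      stage("load", read_curation(p$curation))
    manifest$stages$load <- list(
      n_reads = nrow(reads), n_hits = nrow(hits),
      n_insects = nrow(insects),
      digest = content_digest(unlist(p, use.names = FALSE)))
  }

  counts <- stage("assign", {
    kept <- length_filter(reads, config$rule$min_length)
    top <- select_top_hits(
      filter(hits, .data$query_id %in% kept$read_id), config$rule)
    asg <- consensus_assign(top, refdb$taxonomy, config$rule,
                            query_ids = kept$read_id)
    asg <- apply_curation(asg, curation, refdb$taxonomy)
    utils::write.csv(asg, file.path(config$out_dir, "assignments.csv"),
                     row.names = FALSE)
    tl <- tally_pollen(asg, insects)
    utils::write.csv(tl, file.path(config$out_dir, "counts.csv"),
                     row.names = FALSE)
    by_rank <- tapply(asg$query_id, asg$rank, length)
    manifest$stages$assign <- list(
      reads_in = nrow(reads), reads_filtered_out = nrow(reads) - nrow(kept),
      assigned_by_rank = as.list(by_rank),
      digest = content_digest(file.path(config$out_dir, "counts.csv")))
    tl
  })

  profiles <- stage("profiles", {
    pct <- to_percent(counts)
    pa <- to_presence_absence(counts, config$presence_min_reads)
    paj <- jaccard_input_filter(counts, config$rare_above_genus_threshold,
                                config$presence_min_reads)
    utils::write.csv(pct, file.path(config$out_dir, "percent.csv"),
                     row.names = FALSE)
    utils::write.csv(pa, file.path(config$out_dir, "presence_absence.csv"),
                     row.names = FALSE)
    cov <- list_rbind(lapply(sort(unique(insects$site)), function(st) {
      taxa <- pa |>
        inner_join(select(insects, "insect_id", "site"), by = "insect_id") |>
        filter(.data$site == st) |>
        distinct(.data$taxon, .data$rank)
      entomophilous_coverage(site_plants, taxa, st,
                             taxonomy = refdb$taxonomy)
    }))
    utils::write.csv(cov, file.path(config$out_dir, "coverage.csv"),
                     row.names = FALSE)
    manifest$stages$profiles <- list(
      n_insects_percent = length(unique(pct$insect_id)),
      n_taxa_presence = length(unique(pa$taxon)),
      digest = content_digest(file.path(config$out_dir,
                                        "presence_absence.csv")))
    list(pct = pct, pa = pa, paj = paj, cov = cov)
  })

  networks <- stage("networks", {
    res <- lapply(sort(unique(insects$site)), function(st) {
      mat <- build_network(profiles$pa, insects, st)
      write_matrix_csv(mat, file.path(config$out_dir,
                                      paste0("network_", st, ".csv")))
      list(site = st, h2 = network_h2prime(mat), d = species_dprime(mat))
    })
    metrics <- list(
      h2 = list_rbind(lapply(res, function(r) glance(r$h2))),
      dprime = list_rbind(lapply(res, function(r) r$d)))
    jsonlite::write_json(metrics,
                         file.path(config$out_dir, "network_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$networks <- list(
      n_sites = length(res),
      digest = content_digest(file.path(config$out_dir,
                                        "network_metrics.json")))
    metrics
  })

  stats_out <- stage("stats", {
    d <- jaccard_distances(profiles$paj)
    suite <- run_contrast_battery(d, insects, alpha = config$alpha,
                                  n_perm = config$n_perm,
                                  seed = child_seed(config$seed, "stats"))
    kw <- kruskal_wallis(networks$dprime, dprime, species)
    out <- list(contrasts = as.data.frame(suite),
                sidak_cutoff = attr(suite, "sidak_cutoff"),
                alpha = attr(suite, "alpha"), k = attr(suite, "k"),
                kruskal_wallis = glance(kw))
    jsonlite::write_json(out, file.path(config$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$stats <- list(
      n_contrasts = nrow(suite),
      digest = content_digest(file.path(config$out_dir, "stats.json")))
    out
  })

  manifest$outputs <- list.files(config$out_dir, recursive = TRUE)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipe_log(config, "done", paste0(length(manifest$stages), " stages"))
  invisible(manifest)
}

empty_curation <- function() {
  tibble(rule_type = character(), key = character(),
         new_rank = character(), new_label = character())
}
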