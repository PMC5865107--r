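#' Jaccard distances between pollen loads
#'
#' Classic binary Jaccard distance, `1 - |intersection| / |union|`, between
#' the presence/absence profiles of every pair of insects. Insects with an
#' empty profile cannot be placed and are dropped with a warning (an error
#' if nothing remains). The result is a metric (zero diagonal, symmetry,
#' triangle inequality).
#'
#' @param pa Long presence tibble (`insect_id`, `taxon`), e.g. from
#'   [jaccard_input_filter()].
#' @return A [stats::dist] with insect ids as labels.
#' @export
jaccard_distances <- function(pa) {
  m <- long_to_matrix(mutate(distinct(pa, .data$insect_id, .data$taxon),
                             present = 1),
                      "insect_id", "taxon", "present")
  keep <- rowSums(m) > 0
  if (!any(keep)) {
    stop_pollinet("all insects have empty profiles", "pollinet_bad_input")
  }
  if (any(!keep)) {
    warn(paste0("dropping insect(s) with empty profiles: ",
                paste(head(rownames(m)[!keep], 5), collapse = ", ")))
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) < 2) {
    stop_pollinet("need at least two insects with non-empty profiles",
                  "pollinet_bad_input")
  }
  inter <- m %*% t(m)
  sz <- rowSums(m)
  un <- outer(sz, sz, "+") - inter
  d <- 1 - inter / un
  stats::as.dist(d)
}

#' Permutational MANOVA (one factor, optional strata)
#'
#' Partitions the total sum of squared distances into between- and
#' within-group components via the Gower identity
#' (`SS_total = sum_{i<j} d_ij^2 / n`, `SS_within = sum_g sum_{i<j in g}
#' d_ij^2 / n_g`) and forms the pseudo-F
#' `(SS_between / (k - 1)) / (SS_within / (n - k))`. Significance comes
#' from permuting group labels; when `strata` is given, labels are shuffled
#' only within each stratum (insects from one collection site never swap
#' with another site's), the exchangeability restriction appropriate when
#' samples are clustered by site. The p-value uses the add-one estimator
#' `(1 + #{F* >= F}) / (1 + n_perm)`, so it is never exactly zero and has
#' resolution `1 / (n_perm + 1)`. A degenerate fit with `SS_within = 0`
#' reports F as `Inf`; permuted relabellings that also reach `SS_within = 0`
#' count as ties, so p stays honest rather than collapsing to the
#' resolution floor.
#'
#' @param d A [stats::dist] or symmetric distance matrix with labels.
#' @param groups Grouping factor, either a vector aligned with the distance
#'   labels or a named vector keyed by label.
#' @param strata Optional stratum labels (same conventions as `groups`).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed for the permutation stream; required for exact
#'   reproducibility.
#' @return List of class `permanova`: `F`, `R2`, `p`, `df_between`,
#'   `df_resid`, `n`, `k`, `n_perm`, `seed`, `ss` (named components).
#' @export
permanova <- function(d, groups, strata = NULL, n_perm = 9999L,
                      seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  labels <- rownames(dm)
  groups <- align_labels(groups, labels, "groups")
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) {
    stop_pollinet("need at least two groups", "pollinet_bad_input")
  }
  if (!is.null(strata)) {
    strata <- factor(align_labels(strata, labels, "strata"))
    lone <- tapply(seq_len(n), strata, length) == 1
    if (any(lone)) {
      warn(paste0("stratum(-a) of size 1 cannot be permuted: ",
                  paste(names(lone)[lone], collapse = ", ")))
    }
  }
  d2 <- dm^2
  ss <- permanova_ss(d2, groups)
  fobs <- permanova_f(ss, n, k)
  if (!is.null(seed)) set.seed(as.integer(seed))
  count_ge <- 0L
  perm_idx <- seq_len(n)
  strata_split <- if (is.null(strata)) list(seq_len(n)) else
    split(seq_len(n), strata)
  for (b in seq_len(n_perm)) {
    idx <- perm_idx
    for (s in strata_split) {
      if (length(s) > 1) idx[s] <- s[sample.int(length(s))]
    }
    ssp <- permanova_ss(d2, groups[idx])
    if (permanova_f(ssp, n, k) >= fobs - 1e-12) count_ge <- count_ge + 1L
  }
  p <- (1 + count_ge) / (1 + n_perm)
  structure(list(F = fobs, R2 = ss$between / ss$total, p = p,
                 df_between = k - 1L, df_resid = n - k, n = n, k = k,
                 n_perm = as.integer(n_perm), seed = seed,
                 ss = c(between = ss$between, within = ss$within,
                        total = ss$total)),
            class = "permanova")
}

align_labels <- function(x, labels, what) {
  if (!is.null(names(x)) && !is.null(labels)) {
    if (!all(labels %in% names(x))) {
      stop_pollinet(paste0(what, " is missing label(s): ",
                           paste(head(setdiff(labels, names(x)), 5),
                                 collapse = ", ")),
                    "pollinet_bad_input")
    }
    return(unname(x[labels]))
  }
  if (length(x) != length(labels)) {
    stop_pollinet(paste0(what, " must have one entry per sample"),
                  "pollinet_bad_input")
  }
  x
}

permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  total <- sum(d2) / (2 * n)
  within <- 0
  for (g in levels(groups)) {
    i <- which(groups == g)
    if (length(i) > 1) {
      within <- within + sum(d2[i, i]) / (2 * length(i))
    }
  }
  list(total = total, within = within, between = total - within)
}

permanova_f <- function(ss, n, k) {
  if (ss$within <= 0) return(Inf)
  (ss$between / (k - 1)) / (ss$within / (n - k))
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "Permutational MANOVA: F(%d, %d) = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
    x$df_between, x$df_resid, x$F, x$R2, x$p, x$n_perm))
  invisible(x)
}

#' @method tidy permanova
#' @export
tidy.permanova <- function(x, ...) {
  tibble(term = c("between", "within", "total"),
         df = c(x$df_between, x$df_resid, x$n - 1L),
         sum_of_squares = unname(x$ss[c("between", "within", "total")]),
         statistic = c(x$F, NA, NA),
         R2 = c(x$R2, 1 - x$R2, 1),
         p.value = c(x$p, NA, NA))
}

#' @method glance permanova
#' @export
glance.permanova <- function(x, ...) {
  tibble(statistic = x$F, R2 = x$R2, p.value = x$p,
         df_between = x$df_between, df_resid = x$df_resid, n = x$n,
         n_perm = x$n_perm)
}

#' Dunn-Sidak per-test cutoff
#'
#' `1 - (1 - alpha)^(1/k)`: the per-comparison significance level that
#' controls the family-wise error at `alpha` over `k` independent tests.
#'
#' @param alpha Family-wise error rate.
#' @param k Number of comparisons.
#' @return The per-test cutoff.
#' @export
sidak_cutoff <- function(alpha = 0.05, k) {
  if (!is_count(k) || k < 1) {
    stop_pollinet("k must be a count >= 1", "pollinet_bad_input")
  }
  1 - (1 - alpha)^(1 / k)
}

#' Build the study's contrast set from insect metadata
#'
#' One one-vs-rest contrast per pollinator genus over all insects, plus one
#' within-genus species contrast for every genus holding more than one
#' species (restricted to that genus's insects). With five genera of which
#' two are multi-species this yields the seven-member correction family.
#'
#' @param insects Insect metadata tibble.
#' @return Named list of contrasts, each a list with `ids` (insects
#'   entering the comparison) and `groups` (named grouping vector).
#' @export
study_contrasts <- function(insects) {
  contrasts <- list()
  for (g in sort(unique(insects$genus))) {
    grp <- ifelse(insects$genus == g, g, "rest")
    contrasts[[paste0(g, "_vs_rest")]] <- list(
      ids = insects$insect_id,
      groups = setNames(grp, insects$insect_id))
  }
  for (g in sort(unique(insects$genus))) {
    sub <- filter(insects, .data$genus == g)
    if (length(unique(sub$pollinator_species)) > 1) {
      contrasts[[paste0(g, "_species")]] <- list(
        ids = sub$insect_id,
        groups = setNames(sub$pollinator_species, sub$insect_id))
    }
  }
  contrasts
}

#' Run a battery of PERMANOVA contrasts with Dunn-Sidak correction
#'
#' Runs one stratified PERMANOVA per contrast and flags significance
#' against the Dunn-Sidak cutoff for the whole family of `k` contrasts.
#'
#' @param d Distance matrix ([stats::dist]) over all insects.
#' @param insects Insect metadata (used for strata = site).
#' @param contrasts Named list as from [study_contrasts()] (the default).
#' @param alpha Family-wise error rate.
#' @param n_perm,seed Passed to [permanova()]; each contrast gets a
#'   label-derived sub-seed so the battery is reproducible as a whole.
#' @param strata_by Metadata column defining the permutation strata
#'   (default `"site"`); `NULL` disables strata.
#' @return A tibble of class `comparison_suite`: one row per contrast with
#'   `F`, `R2`, `p`, dfs and `significant`; `alpha`, `k` and
#'   `sidak_cutoff` are attributes.
#' @export
run_contrast_battery <- function(d, insects, contrasts = NULL,
                                 alpha = 0.05, n_perm = 9999L, seed = 1L,
                                 strata_by = "site") {
  contrasts <- contrasts %||% study_contrasts(insects)
  if (length(contrasts) == 0) {
    stop_pollinet("no contrasts to run", "pollinet_bad_input")
  }
  k <- length(contrasts)
  cutoff <- sidak_cutoff(alpha, k)
  dm <- as.matrix(d)
  rows <- imap(contrasts, function(ct, nm) {
    ids <- intersect(rownames(dm), ct$ids)
    groups <- ct$groups[ids]
    if (length(unique(groups)) < 2 || min(table(groups)) < 1) {
      stop_pollinet(paste0("contrast has an empty side: ", nm),
                    "pollinet_bad_input")
    }
    strata <- if (is.null(strata_by)) NULL else
      setNames(insects[[strata_by]], insects$insect_id)[ids]
    res <- permanova(stats::as.dist(dm[ids, ids]), groups, strata = strata,
                     n_perm = n_perm, seed = child_seed(seed, nm))
    tibble(contrast = nm, n = res$n, df_between = res$df_between,
           df_resid = res$df_resid, F = res$F, R2 = res$R2, p = res$p,
           significant = res$p < cutoff)
  })
  out <- list_rbind(rows)
  attr(out, "alpha") <- alpha
  attr(out, "k") <- k
  attr(out, "sidak_cutoff") <- cutoff
  class(out) <- c("comparison_suite", class(out))
  out
}

#' Tie-corrected Kruskal-Wallis test
#'
#' Rank-based k-sample test on a numeric outcome: mid-ranks for ties,
#' `H = [12 / (N (N + 1)) * sum R_g^2 / n_g - 3 (N + 1)]` divided by the
#' tie correction `1 - sum(t^3 - t) / (N^3 - N)`, referred to a chi-square
#' with `groups - 1` degrees of freedom. All-identical values leave the
#' statistic undefined and raise an error.
#'
#' @param data Data frame holding the outcome and grouping columns.
#' @param values Column of numeric values (tidy-eval).
#' @param groups Column of group labels (tidy-eval).
#' @return List of class `kruskal_wallis`: `statistic` (H), `df`,
#'   `p.value`, `n`, `k`.
#' @export
kruskal_wallis <- function(data, values, groups) {
  x <- dplyr::pull(data, {{ values }})
  g <- factor(dplyr::pull(data, {{ groups }}))
  if (nlevels(g) < 2) {
    stop_pollinet("need at least two groups", "pollinet_bad_input")
  }
  if (length(unique(x)) == 1) {
    stop_pollinet("all values identical: statistic undefined",
                  "pollinet_bad_input")
  }
  N <- length(x)
  r <- rank(x)  # mid-ranks for ties
  Rg <- tapply(r, g, sum)
  ng <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / corr
  df <- nlevels(g) - 1L
  structure(list(statistic = H, df = df,
                 p.value = pchisq(H, df, lower.tail = FALSE),
                 n = N, k = nlevels(g)),
            class = "kruskal_wallis")
}

#' @export
print.kruskal_wallis <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @method glance kruskal_wallis
#' @export
glance.kruskal_wallis <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         n = x$n, k = x$k)
}
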