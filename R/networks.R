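# Bipartite specialisation indices computed from first principles.
#
# The observed interaction matrix a_ij (pollinator species i, plant taxon j)
# defines p_ij = a_ij / m with m the grand total. Network-level two-
# dimensional Shannon entropy H2 = -sum p_ij ln p_ij is standardised between
# the maximum achievable under the marginal totals (the independence table)
# and the minimum (the most concentrated integer table honouring the
# marginals): H2' = (H2max - H2) / (H2max - H2min). Species-level d is the
# Kullback-Leibler divergence of the row's partner-use distribution from
# partner availability q_j = B_j / m (availability includes the focal row),
# standardised between its own integer-feasible minimum and ln(m / A_i).
# Natural logarithms throughout.

#' Build a per-site interaction matrix
#'
#' Aggregates individual presence/absence profiles into a pollinator-species
#' by plant-taxon matrix for one site: cell (i, j) counts the individuals of
#' species i at the site whose profile includes taxon j. The per-individual
#' aggregation is stated explicitly because species-level metrics are
#' computed from individual presence/absence records. All-zero rows and
#' columns are removed.
#'
#' @param pa Long presence tibble (`insect_id`, `taxon`) from
#'   [to_presence_absence()].
#' @param insects Insect metadata tibble.
#' @param site Site label; a site with no insects is an error.
#' @return Integer matrix of class `interaction_matrix` with the site in
#'   attribute `"site"`.
#' @export
build_network <- function(pa, insects, site) {
  members <- filter(insects, .data$site == !!site)
  if (nrow(members) == 0) {
    stop_pollinet(paste0("no insects at site: ", site),
                  "pollinet_bad_input")
  }
  df <- pa |>
    inner_join(select(members, "insect_id", "pollinator_species"),
               by = "insect_id") |>
    distinct(.data$insect_id, .data$pollinator_species, .data$taxon) |>
    count(.data$pollinator_species, .data$taxon, name = "n_individuals")
  if (nrow(df) == 0) {
    stop_pollinet(paste0("no presences at site: ", site),
                  "pollinet_bad_input")
  }
  m <- long_to_matrix(df, "pollinator_species", "taxon", "n_individuals")
  storage.mode(m) <- "integer"
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  structure(m, class = c("interaction_matrix", class(m)), site = site)
}

shannon <- function(x) {
  p <- x[x > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

# Greedy concentration heuristic for the minimum-entropy table: repeatedly
# allocate min(remaining row, remaining column) to the cell pairing the
# largest remaining row with the largest remaining column; ties broken by
# index (label) order. Always feasible, so always an upper bound on the
# exact minimum entropy.
h2_min_greedy <- function(row_totals, col_totals) {
  r <- as.numeric(row_totals)
  cc <- as.numeric(col_totals)
  cells <- numeric(0)
  while (sum(r) > 0) {
    i <- which.max(r)
    j <- which.max(cc)
    x <- min(r[i], cc[j])
    cells <- c(cells, x)
    r[i] <- r[i] - x
    cc[j] <- cc[j] - x
  }
  shannon(cells)
}

# Exact minimum entropy over all non-negative integer tables with the given
# marginals, by depth-first enumeration. Only called for small problems.
h2_min_exact <- function(row_totals, col_totals) {
  nr <- length(row_totals)
  nc <- length(col_totals)
  m <- sum(row_totals)
  best <- Inf
  cells <- numeric(nr * nc)
  recurse_row <- function(i, colrem, pos) {
    if (i > nr) {
      h <- shannon(cells[seq_len(pos - 1)])
      if (h < best) best <<- h
      return(invisible())
    }
    target <- row_totals[i]
    comp <- function(j, rem, pos) {
      if (j == nc) {
        if (rem <= colrem[nc]) {
          cells[pos] <<- rem
          cr <- colrem
          cr[nc] <- cr[nc] - rem
          for (jj in seq_len(nc - 1)) {
            cr[jj] <- cr[jj] - cells[pos - nc + jj]
          }
          recurse_row(i + 1, cr, pos + 1)
        }
        return(invisible())
      }
      for (v in 0:min(rem, colrem[j])) {
        cells[pos] <<- v
        comp(j + 1, rem - v, pos + 1)
      }
    }
    comp(1, target, pos)
  }
  recurse_row(1, col_totals, 1)
  best
}

h2_bounds <- function(row_totals, col_totals, force_heuristic = FALSE,
                      exact_max_m = 12L, exact_max_dim = 4L) {
  m <- sum(row_totals)
  # Maximum entropy under fixed marginals: the (generally non-integer)
  # independence table A_i B_j / m.
  p <- outer(row_totals / m, col_totals / m)
  h2max <- -sum(p[p > 0] * log(p[p > 0]))
  exact_ok <- !force_heuristic && m <= exact_max_m &&
    length(row_totals) <= exact_max_dim && length(col_totals) <= exact_max_dim
  h2min <- if (exact_ok) {
    h2_min_exact(row_totals, col_totals)
  } else {
    h2_min_greedy(row_totals, col_totals)
  }
  list(h2max = h2max, h2min = h2min,
       h2min_method = if (exact_ok) "exact" else "greedy")
}

#' Network-level specialisation H2'
#'
#' Computes the two-dimensional Shannon entropy of the interaction matrix
#' and standardises it between the marginal-constrained maximum (the
#' independence table) and minimum (exact integer minimisation when the
#' grand total is at most `exact_max_m` and both dimensions at most
#' `exact_max_dim`; a greedy concentration heuristic otherwise). H2' is 0
#' for perfect generalisation and 1 for perfect specialisation. Because the
#' maximum uses the continuous independence table while the minimum is an
#' integer table, the standardised value can marginally overshoot [0, 1];
#' it is then clipped with a warning. Matrices with a single row or column
#' are degenerate: H2' is undefined and returned as `NA` with
#' `degenerate = TRUE`.
#'
#' @param mat Integer interaction matrix (rows: pollinator species,
#'   columns: plant taxa).
#' @param force_heuristic If `TRUE`, never switch to the exact enumeration
#'   (used to study the heuristic itself).
#' @param exact_max_m,exact_max_dim Size limits of the exact minimisation.
#' @return List of class `network_specialization`: `site`, `H2`, `H2max`,
#'   `H2min`, `H2prime`, `degenerate`, `h2min_method`, `m`.
#' @export
network_h2prime <- function(mat, force_heuristic = FALSE,
                            exact_max_m = 12L, exact_max_dim = 4L) {
  mat <- check_interaction_matrix(mat)
  m <- sum(mat)
  h2 <- shannon(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    out <- list(site = attr(mat, "site"), H2 = h2, H2max = NA_real_,
                H2min = NA_real_, H2prime = NA_real_, degenerate = TRUE,
                h2min_method = NA_character_, m = m)
    return(structure(out, class = "network_specialization"))
  }
  b <- h2_bounds(rowSums(mat), colSums(mat),
                 force_heuristic = force_heuristic,
                 exact_max_m = exact_max_m, exact_max_dim = exact_max_dim)
  denom <- b$h2max - b$h2min
  h2prime <- if (denom > 0) (b$h2max - h2) / denom else 0
  if (h2prime < 0 || h2prime > 1) {
    warn(sprintf("H2' = %.6f outside [0, 1] (integer bounds); clipping",
                 h2prime))
    h2prime <- min(1, max(0, h2prime))
  }
  structure(list(site = attr(mat, "site"), H2 = h2, H2max = b$h2max,
                 H2min = b$h2min, H2prime = h2prime, degenerate = FALSE,
                 h2min_method = b$h2min_method, m = m),
            class = "network_specialization")
}

#' @export
print.network_specialization <- function(x, ...) {
  if (x$degenerate) {
    cat("<network_specialization> degenerate matrix (one row or column);",
        "H2' undefined\n")
  } else {
    cat(sprintf(
      "<network_specialization>%s H2 = %.4f  [min %.4f, max %.4f]  H2' = %.4f\n",
      if (is.null(x$site)) "" else paste0(" site ", x$site, ":"),
      x$H2, x$H2min, x$H2max, x$H2prime))
  }
  invisible(x)
}

# Largest-remainder integer allocation of A units proportional to shares q;
# ties in the remainders broken by index order.
largest_remainder <- function(A, q) {
  target <- A * q
  base <- floor(target)
  rem <- A - sum(base)
  if (rem > 0) {
    frac <- target - base
    ord <- order(-frac, seq_along(q))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

kl_div <- function(a, A, q) {
  i <- a > 0
  sum((a[i] / A) * log((a[i] / A) / q[i]))
}

# Exact minimum KL divergence over all compositions of A across the columns.
d_min_exact <- function(A, q) {
  nc <- length(q)
  best <- Inf
  alloc <- integer(nc)
  rec <- function(j, rem) {
    if (j == nc) {
      alloc[nc] <<- rem
      v <- kl_div(alloc, A, q)
      if (v < best) best <<- v
      return(invisible())
    }
    for (v in 0:rem) {
      alloc[j] <<- v
      rec(j + 1, rem - v)
    }
  }
  rec(1, A)
  best
}

d_min_bound <- function(A, q, force_heuristic = FALSE, exact_max_a = 10L,
                        exact_max_cols = 5L) {
  exact_ok <- !force_heuristic && A <= exact_max_a &&
    length(q) <= exact_max_cols
  if (exact_ok) {
    list(dmin = d_min_exact(A, q), method = "exact")
  } else {
    list(dmin = kl_div(largest_remainder(A, q), A, q),
         method = "largest_remainder")
  }
}

#' Species-level specialisation d'
#'
#' For each pollinator species (row) computes d, the Kullback-Leibler
#' divergence of its partner-use distribution a_ij / A_i from overall
#' partner availability q_j = B_j / m (availability includes the focal
#' row's own interactions), and standardises it between the minimum d of an
#' integer-feasible allocation of A_i interactions (exact enumeration of
#' compositions when A_i is at most `exact_max_a` over at most
#' `exact_max_cols` columns, largest-remainder allocation otherwise) and
#' the maximum ln(m / A_i). d' is 0 for no exclusivity and 1 for complete
#' exclusivity. A single-column matrix has dmax = dmin; d' is then 0 by
#' convention, with a warning.
#'
#' @inheritParams network_h2prime
#' @param exact_max_a,exact_max_cols Size limits of the exact minimisation.
#' @return Tibble with `species`, `d`, `dmin`, `dmax`, `dprime`,
#'   `dmin_method` (plus a `site` column when the matrix carries one).
#' @export
species_dprime <- function(mat, force_heuristic = FALSE, exact_max_a = 10L,
                           exact_max_cols = 5L) {
  mat <- check_interaction_matrix(mat)
  m <- sum(mat)
  A <- rowSums(mat)
  if (any(A < 1)) {
    stop_pollinet("interaction matrix has an all-zero row",
                  "pollinet_bad_input")
  }
  q <- colSums(mat) / m
  if (ncol(mat) == 1) {
    warn("single-column matrix: dmax = dmin, d' set to 0")
  }
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    Ai <- unname(A[i])
    d <- unname(kl_div(mat[i, ], Ai, q))
    dmax <- log(m / Ai)
    b <- d_min_bound(Ai, q, force_heuristic = force_heuristic,
                     exact_max_a = exact_max_a,
                     exact_max_cols = exact_max_cols)
    dprime <- if (dmax - b$dmin > 0) (d - b$dmin) / (dmax - b$dmin) else 0
    dprime <- min(1, max(0, dprime))
    tibble(species = rownames(mat)[i], d = d, dmin = b$dmin, dmax = dmax,
           dprime = dprime, dmin_method = b$method)
  })
  out <- list_rbind(rows)
  if (!is.null(attr(mat, "site"))) {
    out <- mutate(out, site = attr(mat, "site"), .before = 1)
  }
  out
}

check_interaction_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop_pollinet("interaction matrix must be a numeric matrix",
                  "pollinet_bad_input")
  }
  if (any(mat < 0) || any(mat != floor(mat))) {
    stop_pollinet("interaction matrix cells must be non-negative integers",
                  "pollinet_bad_input")
  }
  if (sum(mat) < 1) {
    stop_pollinet("interaction matrix has zero grand total",
                  "pollinet_bad_input")
  }
  mat
}

#' Tidy an interaction matrix
#'
#' @param x An `interaction_matrix`.
#' @param ... Unused.
#' @return Long tibble `pollinator_species`, `taxon`, `n_individuals` (plus
#'   `site`), non-zero cells only.
#' @method tidy interaction_matrix
#' @export
tidy.interaction_matrix <- function(x, ...) {
  idx <- which(x > 0, arr.ind = TRUE)
  out <- tibble(pollinator_species = rownames(x)[idx[, 1]],
                taxon = colnames(x)[idx[, 2]],
                n_individuals = x[idx])
  if (!is.null(attr(x, "site"))) {
    out <- mutate(out, site = attr(x, "site"), .before = 1)
  }
  arrange(out, .data$pollinator_species, .data$taxon)
}

#' @method glance network_specialization
#' @export
glance.network_specialization <- function(x, ...) {
  tibble(site = x$site %||% NA_character_, m = x$m, H2 = x$H2,
         H2min = x$H2min, H2max = x$H2max, H2prime = x$H2prime,
         degenerate = x$degenerate)
}
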