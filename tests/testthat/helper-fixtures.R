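# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

toy_taxonomy <- function() {
  tibble::tibble(
    ref_id = c("r1", "r2", "r3", "r4", "r5", "r6"),
    species = c("Succisa pratensis", "Cirsium dissectum", "Cirsium arvense",
                "Calluna vulgaris", NA, NA),
    genus = c("Succisa", "Cirsium", "Cirsium", "Calluna", "Heracleum", NA),
    tribe = c(NA, "Cardueae", "Cardueae", NA, NA, NA),
    family = c("Caprifoliaceae", "Asteraceae", "Asteraceae", "Ericaceae",
               "Apiaceae", "Poaceae"))
}

toy_insects <- function() {
  tibble::tibble(
    insect_id = c("i1", "i2", "i3", "i4"),
    pollinator_species = c("Eristalis tenax", "Eristalis tenax",
                           "Rhingia campestris", "Sericomyia silentis"),
    genus = c("Eristalis", "Eristalis", "Rhingia", "Sericomyia"),
    site = c("CAD", "CAD", "LLC", "LLC"))
}

toy_counts <- function() {
  tibble::tibble(
    insect_id = c("i1", "i1", "i1", "i2", "i2", "i3", "i4"),
    taxon = c("Succisa pratensis", "Cirsium", "unknown",
              "Succisa pratensis", "Asteraceae",
              "Cirsium", "unknown"),
    rank = c("species", "genus", "unknown",
             "species", "family", "genus", "unknown"),
    count = c(50L, 30L, 20L, 10L, 1L, 5L, 7L))
}

tiny_sim_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_sites = 2L, n_families = 2L,
                   genera_per_family = 3L, species_per_genus = 2L,
                   n_pollinator_species = 6L, n_pollinator_genera = 3L,
                   individuals_per_species_site = 2L,
                   reads_per_individual = 40L, ref_length = 300L,
                   read_error_rate = 0.003)
  do.call(pollinet::sim_config, utils::modifyList(defaults, list(...)))
}

# --- independent oracles (used only to check the package's computations) ---

oracle_entropy <- function(a) {
  p <- a[a > 0] / sum(a)
  -sum(p * log(p))
}

# Exact minimum entropy over integer tables with fixed margins, written as a
# plain nested-loop enumeration over the free (upper-left) cells so it shares
# nothing with the package's recursive implementation. Supports up to 3x3.
oracle_h2min <- function(rt, ct) {
  rt <- rt[rt > 0]; ct <- ct[ct > 0]
  nr <- length(rt); nc <- length(ct)
  stopifnot(nr <= 3, nc <= 3)
  pad <- function(x, n) c(x, rep(0, n - length(x)))
  rt <- pad(rt, 3); ct <- pad(ct, 3)
  best <- Inf
  for (a11 in 0:min(rt[1], ct[1]))
    for (a12 in 0:min(rt[1] - a11, ct[2]))
      for (a21 in 0:min(rt[2], ct[1] - a11))
        for (a22 in 0:min(rt[2] - a21, ct[2] - a12)) {
          a13 <- rt[1] - a11 - a12
          a23 <- rt[2] - a21 - a22
          a31 <- ct[1] - a11 - a21
          a32 <- ct[2] - a12 - a22
          a33 <- rt[3] - a31 - a32
          cells <- c(a11, a12, a13, a21, a22, a23, a31, a32, a33)
          if (any(cells < 0) || a13 + a23 + a33 != ct[3]) next
          h <- oracle_entropy(cells)
          if (h < best) best <- h
        }
  best
}

oracle_kl <- function(a, A, q) {
  i <- a > 0
  sum((a[i] / A) * log((a[i] / A) / q[i]))
}

# Exact minimum KL over all compositions of A into length(q) parts,
# enumerated through utils::combn on stars-and-bars positions.
oracle_dmin <- function(A, q) {
  k <- length(q)
  if (k == 1) return(0)
  bars <- utils::combn(A + k - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(bars))) {
    cuts <- c(0, bars[, j], A + k)
    a <- diff(cuts) - 1
    stopifnot(sum(a) == A, all(a >= 0))
    v <- oracle_kl(a, A, q)
    if (v < best) best <- v
  }
  best
}

# All partitions of m into at most `parts` positive parts, sorted descending.
partitions_leq <- function(m, parts = 3) {
  out <- list()
  rec <- function(rem, maxpart, acc) {
    if (rem == 0) {
      out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    if (length(acc) == parts) return(invisible())
    for (v in min(rem, maxpart):1) rec(rem - v, v, c(acc, v))
  }
  rec(m, m, integer(0))
  out
}

random_pa_long <- function(n_insects, n_taxa, p = 0.5) {
  m <- matrix(stats::rbinom(n_insects * n_taxa, 1, p), n_insects, n_taxa)
  empty <- rowSums(m) == 0
  m[empty, sample.int(n_taxa, sum(empty), replace = TRUE)] <- 1
  idx <- which(m == 1, arr.ind = TRUE)
  tibble::tibble(insect_id = sprintf("i%02d", idx[, 1]),
                 taxon = sprintf("t%02d", idx[, 2]))
}
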