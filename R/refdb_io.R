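#' Read a plant barcode reference database
#'
#' Pairs a reference FASTA (one record per barcode sequence) with a taxonomy
#' table mapping each reference id to its ranked lineage (species, genus,
#' tribe, family). Every FASTA id must be present in the taxonomy; lineage
#' rows are validated (non-empty family; a species entry implies a genus
#' entry; unique ids).
#'
#' @param fasta_path Path to the reference FASTA.
#' @param taxonomy_path Path to the taxonomy CSV (columns `ref_id`,
#'   `species`, `genus`, `tribe`, `family`, optionally `native_flag`).
#'   Empty strings are read as missing.
#' @return An object of class `refdb`: a list with `sequences` (named
#'   character vector, IUPAC nucleotides) and `taxonomy` (tibble of
#'   [read_taxonomy()] records restricted and ordered to the FASTA ids).
#' @export
read_reference <- function(fasta_path, taxonomy_path) {
  seqs <- read_fasta(fasta_path)
  if (length(seqs) == 0) {
    stop_pollinet("reference FASTA is empty", "pollinet_empty_input")
  }
  bad <- grepl("[^ACGTRYSWKMBDHVN]", toupper(seqs))
  if (any(bad)) {
    stop_pollinet(
      paste0("non-IUPAC characters in reference sequence(s): ",
             paste(head(names(seqs)[bad], 3), collapse = ", ")),
      "pollinet_bad_alphabet")
  }
  taxonomy <- read_taxonomy(taxonomy_path)
  missing <- setdiff(names(seqs), taxonomy$ref_id)
  if (length(missing) > 0) {
    stop_pollinet(
      paste0("reference id(s) absent from taxonomy: ",
             paste(head(missing, 5), collapse = ", ")),
      "pollinet_missing_taxonomy")
  }
  taxonomy <- taxonomy[match(names(seqs), taxonomy$ref_id), ]
  new_refdb(setNames(toupper(unname(seqs)), names(seqs)), taxonomy)
}

new_refdb <- function(sequences, taxonomy) {
  structure(list(sequences = sequences, taxonomy = taxonomy),
            class = "refdb")
}

#' @export
print.refdb <- function(x, ...) {
  cat("<refdb> ", length(x$sequences), " reference sequences, ",
      length(unique(x$taxonomy$family)), " families\n", sep = "")
  invisible(x)
}

#' Read a taxonomy table
#'
#' @param path CSV with columns `ref_id`, `species`, `genus`, `tribe`,
#'   `family` and optionally `native_flag`. Blank cells denote absent ranks.
#' @return A tibble with one row per reference id; character ranks use `NA`
#'   for absent entries. Labels are treated as case-sensitive opaque strings
#'   (whitespace-trimmed only).
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("ref_id", "species", "genus", "tribe", "family")
  if (!all(need %in% names(df))) {
    stop_pollinet(
      paste0("taxonomy is missing column(s): ",
             paste(setdiff(need, names(df)), collapse = ", ")),
      "pollinet_bad_columns")
  }
  out <- as_tibble(df[, intersect(c(need, "native_flag"), names(df))])
  for (col in need) {
    out[[col]] <- trim_ws(out[[col]])
    out[[col]][out[[col]] == ""] <- NA_character_
  }
  if ("native_flag" %in% names(out)) {
    out$native_flag <- as.logical(out$native_flag)
  }
  validate_taxonomy(out)
  out
}

validate_taxonomy <- function(tax) {
  if (anyDuplicated(tax$ref_id)) {
    stop_pollinet(
      paste0("duplicate ref_id in taxonomy: ",
             paste(head(unique(tax$ref_id[duplicated(tax$ref_id)]), 3),
                   collapse = ", ")),
      "pollinet_duplicate_id")
  }
  if (anyNA(tax$family)) {
    stop_pollinet("taxonomy rows with empty family", "pollinet_bad_lineage")
  }
  orphan <- !is.na(tax$species) & is.na(tax$genus)
  if (any(orphan)) {
    stop_pollinet(
      paste0("species set but genus blank for ref_id: ",
             paste(head(tax$ref_id[orphan], 3), collapse = ", ")),
      "pollinet_bad_lineage")
  }
  invisible(tax)
}

#' Read a tabular alignment hit file
#'
#' Parses the classic 12-column tab-separated alignment format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`). The dialect is fixed: rows with any other column count
#' are rejected with their line number, so silent column drift cannot pass.
#' Row order within a query carries no meaning downstream.
#'
#' @param path Path to the hit TSV. An empty file yields an empty table with
#'   a warning.
#' @return A tibble with columns `query_id`, `subject_id`,
#'   `percent_identity`, `align_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `e_value`, `bit_score`.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("query_id", "subject_id", "percent_identity", "align_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "e_value", "bit_score")
  if (length(lines) == 0) {
    warn("hit table is empty")
    out <- as_tibble(setNames(
      c(list(character(), character()), rep(list(numeric()), 10)), cols))
    out$align_length <- integer()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12)) {
    i <- which(nf != 12)[1]
    stop_pollinet(
      sprintf("hit table line %d has %d columns (expected 12)", i, nf[i]),
      "pollinet_parse_error")
  }
  m <- matrix(unlist(parts), ncol = 12, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10)
  if (anyNA(num)) {
    i <- which(rowSums(is.na(num)) > 0)[1]
    stop_pollinet(
      sprintf("hit table line %d has a non-numeric field", i),
      "pollinet_parse_error")
  }
  out <- tibble(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = num[, 1], align_length = as.integer(num[, 2]),
    mismatches = as.integer(num[, 3]), gap_opens = as.integer(num[, 4]),
    q_start = as.integer(num[, 5]), q_end = as.integer(num[, 6]),
    s_start = as.integer(num[, 7]), s_end = as.integer(num[, 8]),
    e_value = num[, 9], bit_score = num[, 10])
  validate_hits(out)
  arrange(out, .data$query_id)
}

validate_hits <- function(hits) {
  if (any(hits$bit_score < 0)) {
    stop_pollinet("negative bit score in hit table", "pollinet_bad_value")
  }
  if (any(hits$align_length < 1)) {
    stop_pollinet("alignment length < 1 in hit table", "pollinet_bad_value")
  }
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    stop_pollinet("percent identity outside [0, 100]", "pollinet_bad_value")
  }
  invisible(hits)
}

#' Write a hit table in the 12-column tabular dialect
#'
#' @param hits A tibble as returned by [read_hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  m <- cbind(hits$query_id, hits$subject_id,
             format_num(hits$percent_identity), hits$align_length,
             hits$mismatches, hits$gap_opens, hits$q_start, hits$q_end,
             hits$s_start, hits$s_end, format_num(hits$e_value),
             format_num(hits$bit_score))
  writeLines(apply(m, 1, paste, collapse = "\t"), path)
  invisible(path)
}

format_num <- function(x) {
  vapply(x, function(v) format(v, scientific = v != 0 && abs(v) < 1e-3,
                               digits = 6, trim = TRUE), character(1))
}

#' Read insect metadata
#'
#' @param path CSV with columns `insect_id`, `pollinator_species`, `site`
#'   and optionally `genus` (defaults to the first word of the species
#'   binomial).
#' @return Tibble with columns `insect_id`, `pollinator_species`, `genus`,
#'   `site`.
#' @export
read_insects <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("insect_id", "pollinator_species", "site")
  if (!all(need %in% names(df))) {
    stop_pollinet(
      paste0("insect metadata is missing column(s): ",
             paste(setdiff(need, names(df)), collapse = ", ")),
      "pollinet_bad_columns")
  }
  out <- as_tibble(df)
  for (col in names(out)) out[[col]] <- trim_ws(out[[col]])
  if (!"genus" %in% names(out)) {
    out$genus <- sub("\\s.*$", "", out$pollinator_species)
  }
  if (anyDuplicated(out$insect_id)) {
    stop_pollinet("duplicate insect_id in metadata", "pollinet_duplicate_id")
  }
  select(out, "insect_id", "pollinator_species", "genus", "site")
}

#' Read per-site plant species lists
#'
#' @param path CSV with columns `site`, `plant_species`, `family`.
#' @return Tibble with one row per (site, species) pair.
#' @export
read_site_plants <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("site", "plant_species", "family")
  if (!all(need %in% names(df))) {
    stop_pollinet(
      paste0("site plant list is missing column(s): ",
             paste(setdiff(need, names(df)), collapse = ", ")),
      "pollinet_bad_columns")
  }
  out <- as_tibble(df[, need])
  for (col in need) out[[col]] <- trim_ws(out[[col]])
  if (anyDuplicated(out[, c("site", "plant_species")])) {
    stop_pollinet("duplicate (site, plant_species) rows",
                  "pollinet_duplicate_id")
  }
  out
}

#' Read a curation map
#'
#' Ordered rules that resolve consensus assignments of rank `various` to
#' family or tribe level (or to `unknown`). `rule_type` is either
#' `"signature"` (matched against the sorted `|`-joined set of families among
#' a read's retained hits) or `"query"` (matched against an explicit read
#' id). The first matching rule wins; unmatched `various` reads fall through
#' to `unknown`.
#'
#' @param path CSV with columns `rule_type`, `key`, `new_rank`, `new_label`.
#' @return Tibble of curation rules in file order.
#' @export
read_curation <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("rule_type", "key", "new_rank", "new_label")
  if (!all(need %in% names(df))) {
    stop_pollinet(
      paste0("curation map is missing column(s): ",
             paste(setdiff(need, names(df)), collapse = ", ")),
      "pollinet_bad_columns")
  }
  out <- as_tibble(df[, need])
  for (col in need) out[[col]] <- trim_ws(out[[col]])
  bad <- !out$rule_type %in% c("signature", "query")
  if (any(bad)) {
    stop_pollinet("curation rule_type must be 'signature' or 'query'",
                  "pollinet_bad_value")
  }
  bad <- !out$new_rank %in% c("family", "tribe", "unknown")
  if (any(bad)) {
    stop_pollinet("curation new_rank must be family, tribe or unknown",
                  "pollinet_bad_value")
  }
  out
}

#' Write / read a labelled matrix as CSV
#'
#' Round-trip faithful for integer counts and accurate to ~1e-12 for
#' proportions. Row labels go in the first column (`row_label`); labels must
#' be unique and the file rectangular.
#'
#' @param m A matrix with unique row and column names.
#' @param path CSV path.
#' @return `write_matrix_csv()` returns `path` invisibly;
#'   `read_matrix_csv()` returns the matrix.
#' @export
write_matrix_csv <- function(m, path) {
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop_pollinet("matrix must have unique row and column labels",
                  "pollinet_duplicate_id")
  }
  df <- data.frame(row_label = rownames(m),
                   as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "row_label") {
    stop_pollinet("matrix CSV must start with a 'row_label' column",
                  "pollinet_bad_columns")
  }
  if (anyDuplicated(df$row_label) || anyDuplicated(names(df)[-1])) {
    stop_pollinet("duplicate matrix labels", "pollinet_duplicate_id")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    stop_pollinet("matrix CSV has non-numeric cells (ragged file?)",
                  "pollinet_parse_error")
  }
  rownames(m) <- df$row_label
  if (all(m == floor(m))) storage.mode(m) <- "integer"
  m
}

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings that move between files and the named
#' character vectors the simulator and assignment code use.
#'
#' @param path FASTA path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Reads as a tibble
#'
#' @param path FASTA path of (merged) amplicon reads.
#' @return Tibble with columns `read_id`, `sequence`, `length`.
#' @export
read_reads <- function(path) {
  seqs <- read_fasta(path)
  tibble(read_id = names(seqs), sequence = unname(seqs),
         length = nchar(unname(seqs)))
}
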