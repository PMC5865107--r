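# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one top-level seed fans out to labelled
# sub-streams so adding a stage never shifts another stage's draws. All
# arithmetic stays below 2^53 so the modular reduction is exact in doubles.
hash_label <- function(label) {
  h <- 17
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

child_seed <- function(seed, label) {
  as.integer((hash_label(label) + (seed %% 2147483629) * 7919) %% 2147483629)
}

# Evaluate `code` under a derived seed without disturbing the caller's RNG.
with_subseed <- function(seed, label, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(child_seed(seed, label))
  force(code)
}

# FNV-style content hash used for manifest digests (hex string).
content_digest <- function(x) {
  if (length(x) == 1 && is.character(x) && file.exists(x)) {
    x <- readBin(x, "raw", n = file.size(x))
    bytes <- as.integer(x)
  } else {
    bytes <- utf8ToInt(paste(as.character(x), collapse = "\n"))
  }
  h <- 2166136261 %% 2147483629
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

trim_ws <- function(x) gsub("^\\s+|\\s+$", "", x)

stop_pollinet <- function(msg, class) {
  abort(msg, class = c(class, "pollinet_error"))
}

# Long (id, key, value) tibble -> labelled matrix, missing cells filled.
long_to_matrix <- function(df, row, col, value, fill = 0L) {
  rows <- sort(unique(df[[row]]))
  cols <- sort(unique(df[[col]]))
  m <- matrix(fill, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(df[[row]], rows), match(df[[col]], cols))] <- df[[value]]
  m
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}
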