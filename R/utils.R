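# internal helpers shared across modules

PATTERN_ALPHABET <- c("+", "-", "0")

# collation used for all key sorts: '+' < '-' < '0'
# (chartr would read "+-0" as a character range, so substitute stepwise)
key_collate <- function(keys) {
  keys <- gsub("+", "A", keys, fixed = TRUE)
  keys <- gsub("-", "B", keys, fixed = TRUE)
  gsub("0", "C", keys, fixed = TRUE)
}

key_order <- function(keys) {
  order(key_collate(keys), method = "radix")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a 32-bit hash, pure base R; used for deterministic ids and the
# config hash stamped into every export
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; split at 2^16 to stay inside R's
    # 32-bit bitwXor, and multiply by the FNV prime in two halves so the
    # product never loses double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    lo <- bitwXor(lo, b)
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  if (is.null(config)) return("none")
  # the hash identifies the analysis, not where its files land
  keys <- setdiff(sort(names(config)), "out_dir")
  flat <- vapply(keys, function(k) {
    v <- config[[k]]
    paste0(k, "=", paste(format(v, digits = 12), collapse = ","))
  }, character(1))
  fnv1a_hash(paste(flat, collapse = ";"))
}

provenance_line <- function(config = NULL) {
  ver <- as.character(utils::packageVersion("funheatmap"))
  sprintf("# funheatmap %s config=%s", ver, config_hash(config))
}

# fixed-precision number formatting so exports are byte-stable
fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 10)
  out[is.na(x)] <- "NA"
  trimws(out)
}

assert_symbols <- function(key) {
  chars <- strsplit(key, "", fixed = TRUE)
  bad <- !vapply(chars, function(ch) all(ch %in% PATTERN_ALPHABET), logical(1))
  if (any(bad)) {
    stopf("invalid pattern key(s): %s (alphabet is +, -, 0)",
          paste(unique(key[bad]), collapse = ", "))
  }
  invisible(TRUE)
}
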