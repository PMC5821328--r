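#' @useDynLib virowinnow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rbinom rmultinom rnorm runif setNames
#' @importFrom utils read.delim write.table head modifyList
NULL

# Reverse-complement a character vector of DNA sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Translate frame +1 of each sequence; trailing partial codons dropped,
# stops rendered "*", codons containing ambiguity rendered "X".
translate_f1 <- function(x) {
  gc <- Biostrings::GENETIC_CODE
  vapply(x, function(s) {
    L <- nchar(s)
    if (L < 3L) return("")
    starts <- seq.int(1L, L - 2L, by = 3L)
    codons <- substring(toupper(s), starts, starts + 2L)
    aa <- unname(gc[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Round half-up to `digits` decimals (R's round() is banker's rounding;
# printed survey percentages use half-up).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Percent with exact integer numerator/denominator; NA for zero denominator.
pct <- function(num, den, digits = 1) {
  if (den == 0) return(NA_real_)
  round_half_up(100 * num / den, digits)
}

# Deterministic child seeds below 2^31, derived from a user seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2147483647L
}

# Minimal flat YAML reader: "key: value" lines, "#" comments, scalar or
# comma-separated values; numbers auto-coerced. Covers the pipeline and
# simulation config files; nesting is not supported.
read_flat_yaml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    key <- m[2]
    val <- trimws(m[3])
    if (grepl(",", val)) {
      val <- trimws(strsplit(val, ",")[[1]])
    }
    num <- suppressWarnings(as.numeric(val))
    if (!anyNA(num)) val <- num
    out[[key]] <- val
  }
  out
}

write_flat_yaml <- function(x, path) {
  lines <- vapply(names(x), function(k) {
    paste0(k, ": ", paste(x[[k]], collapse = ", "))
  }, character(1))
  writeLines(lines, path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
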