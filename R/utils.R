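#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kgqa <- function(msg, class) {
  stop(structure(class = c(class, "kgqa_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

# lower-case, collapse whitespace; shared by entity linking and templates
normalize_text <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

tokenize <- function(x) {
  x <- normalize_text(x)
  toks <- strsplit(gsub("[^a-z0-9 ]", " ", x), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

# normalized edit similarity in [0, 1]; 1 means identical strings
string_similarity <- function(a, b) {
  a <- normalize_text(a); b <- normalize_text(b)
  d <- utils::adist(a, b)
  m <- pmax(nchar(a), nchar(b))
  s <- 1 - d / pmax(m, 1L)
  s[m == 0L] <- 1
  as.vector(s)
}
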