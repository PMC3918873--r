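## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_real <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  as.numeric(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  x <- check_real(x, name)
  if (x < lo || x > hi)
    stop(sprintf("'%s' must lie in [%g, %g]", name, lo, hi), call. = FALSE)
  x
}

check_genome <- function(genome) {
  if (is.list(genome)) genome <- unlist(genome)
  if (length(genome) == 0 || is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("'genome' must be a named vector of chromosome lengths", call. = FALSE)
  if (any(!is.finite(genome)) || any(genome < 1))
    stop("chromosome lengths must be positive", call. = FALSE)
  stats::setNames(as.numeric(genome), names(genome))
}

## run `expr` under a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

new_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
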