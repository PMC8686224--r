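# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All stochastic steps in the package go
# through this so a single user-facing seed controls everything.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a base seed and a stage label, keeping the result
# in 32-bit integer range so it is a valid R seed.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

log_msg <- function(..., verbose = TRUE, file = NULL) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", paste0(...))
  if (isTRUE(verbose)) message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
  invisible(line)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_sparse <- function(x) methods::is(x, "sparseMatrix")

as_dense <- function(x) {
  if (is_sparse(x)) as.matrix(x) else x
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
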