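#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}

.check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(as.numeric(x))
}

.check_gene_ids <- function(x, name = "genes") {
  x <- as.character(x)
  bad <- !nzchar(x) | grepl("[[:space:]]", x) | is.na(x)
  if (any(bad))
    stop(sprintf("`%s` contains empty or whitespace-containing identifiers", name),
         call. = FALSE)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
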