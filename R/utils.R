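# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# deterministic per-stage substream: offset the global seed by a stage tag
# so stage-level results do not depend on execution order
stage_seed <- function(seed, stage) {
  tag <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + tag * 1009L) %% 2147483647L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_numeric_finite <- function(x, what) {
  if (!is.numeric(x)) stopf("%s must be numeric", what)
  if (anyNA(x) || any(!is.finite(x))) {
    stopf("%s contains missing or non-finite values; inputs are never imputed", what)
  }
  invisible(x)
}

roman_label <- function(i) as.character(utils::as.roman(i))

# md5 of an in-memory object via its canonical text serialization
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(utils::capture.output(dput(x)), f)
  unname(tools::md5sum(f))
}
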