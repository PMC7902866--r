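## Trapezoid quadrature on an ordered grid.
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

.assertScalarNum <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(what, " must be a single finite number", call. = FALSE)
  invisible(x)
}

## Run `expr` with the given seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic per-stage substream: stage seeds derived from the run seed
## and a stage name, kept inside 32-bit integer range.
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 1009 + h) %% 2147483647L)
}

.minmax <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) stop("min-max normalization undefined for a constant vector",
                         call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}
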