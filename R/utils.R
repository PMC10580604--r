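# internal helpers shared across modules

# Evaluate expr under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so generators do not perturb user code.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible per-stage seed from a run seed
#'
#' One global run seed fans out to independent per-stage seeds so that each
#' stage is reproducible in isolation. The derivation hashes the stage tag
#' into a 31-bit integer.
#'
#' @param seed integer run seed.
#' @param tag character stage label, e.g. `"sampling"` or `"extractor:TUM"`.
#' @return an integer in `[0, 2^31 - 1)`.
#' @examples
#' deriveSeed(1L, "sampling")
#' @export
deriveSeed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

# round-half-up (base round() is banker's rounding)
.roundHalfUp <- function(x) floor(x + 0.5)

# md5 of a canonical JSON rendering of a config list
.configHash <- function(cfg) {
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
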