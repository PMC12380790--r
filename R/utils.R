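# Internal helpers: seeded substreams and config fingerprinting.

# Named RNG substreams derived from one master seed, so that toggling one
# randomness source (e.g. background noise) never shifts the draws of the
# others. Offsets are fixed package-wide.
.substream_offsets <- c(
  weights       = 101L,
  heterogeneity = 211L,
  membrane      = 307L,
  threshold     = 401L,
  background    = 503L,
  init          = 601L
)

substream_seed <- function(master_seed, name) {
  off <- .substream_offsets[[name]]
  if (is.null(off)) stop("unknown RNG substream: ", name)
  # keep within 32-bit signed integer range
  as.integer((as.numeric(master_seed) * 7919 + off) %% 2147483647)
}

# Evaluate `expr` under a named substream seed, restoring the caller's RNG
# state afterwards.
with_substream <- function(master_seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(master_seed, name))
  expr
}

# Stable fingerprint of an R object (used to stamp results with the config
# they came from). MD5 of the serialized object, version-2 serialization so
# the hash does not depend on the running R version header.
object_fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
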