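# Internal helpers shared across modules.

# Named pseudo-random streams: each generator draws from its own stream so
# adding a generator never perturbs fixtures produced by another.
.stream_offsets <- c(sets = 101L, affinity = 211L, diseases = 307L,
                     ppi = 401L, gmt = 503L)

stream_seed <- function(seed, stream) {
  if (!stream %in% names(.stream_offsets)) {
    stop("unknown random stream: ", stream)
  }
  (as.integer(seed) %% 1000003L) * 2011L + .stream_offsets[[stream]]
}

with_stream <- function(seed, stream, expr) {
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
  })
  set.seed(stream_seed(seed, stream))
  force(expr)
}

# Separator sniffing for delimited tables: tab wins over comma so that
# comma-containing free-text fields in TSVs survive.
sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return("\t")
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(...) message("[netpharm] ", ...)
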