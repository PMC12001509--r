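#' Derive a reproducible substream seed
#'
#' All randomness in a run flows from one top-level seed; per-image and
#' per-stage seeds are derived deterministically from it and a set of
#' string/integer tags, so that any stage can be re-run in isolation.
#'
#' @param seed integer base seed.
#' @param ... tags (strings or integers) naming the substream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  mod <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% mod)
  for (tag in list(...)) {
    bytes <- utf8ToInt(paste0(as.character(tag), "|"))
    for (b in bytes) h <- (h * 131 + b) %% mod
  }
  as.integer(h %% (mod - 2) + 1)
}

# Atomic file write: run `writer(tmp)` then rename tmp -> path, so a crash
# never leaves a truncated file behind.
write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path)
  invisible(path)
}

# Simple timestamped logger used by the pipeline; writes to a connection
# (or messages when con is NULL).
log_line <- function(con, ...) {
  txt <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
  if (is.null(con)) message(txt) else writeLines(txt, con)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# non-standard-evaluation column names used in ggplot calls
utils::globalVariables(c("condition", "upq_normalized", "q25", "q75", "median"))
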