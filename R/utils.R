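# Internal helpers: seeding, TSV io, argument checks.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed` so that simulation helpers do
#' not perturb the caller's random number stream.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Named substreams: every file type draws from its own deterministic stream
# derived from the single experiment seed. Kept below 2^31 - 1.
substream_seed <- function(seed, stream) {
  offsets <- c(heat = 101L, gas = 211L, otu = 307L, chemistry = 401L,
               rarefy = 503L, perm = 601L, screen = 701L, misc = 811L)
  if (!stream %in% names(offsets)) stop("unknown substream: ", stream)
  (abs(as.integer(seed)) %% 1000000L) * 2048L %% 2147483647L + offsets[[stream]]
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("`", name, "` must be finite numeric", call. = FALSE)
  bad <- if (strict_lower) any(x <= lower) else any(x < lower)
  bad <- bad || if (strict_upper) any(x >= upper) else any(x > upper)
  if (bad) stop("`", name, "` out of range [", lower, ", ", upper, "]",
                call. = FALSE)
  invisible(x)
}
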