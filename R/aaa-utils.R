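# Internal helpers shared across modules.

# Sleep-stage alphabet and the [0,1] codes used in the model-input tensor.
STAGE_LEVELS <- c("W", "N1", "N2", "N3", "REM")
STAGE_CODES <- c(W = 0, N1 = 0.25, N2 = 0.5, N3 = 0.75, REM = 1)

# Canonical EEG montage (scalp + mastoids) and the 11 baseline features used
# for responder prediction, in their fixed documented order.
EEG_CHANNELS <- c("F3", "F4", "C3", "C4", "O1", "O2", "A1", "A2")
SCALP_CHANNELS <- c("F3", "C3", "O1", "F4", "C4", "O2")
FEATURES_CANONICAL <- c("bai", "age", "sex", "ai", "ahi", "apnea_index",
                        "hypopnea_index", "odi", "hb_total", "hb_apnea",
                        "hb_hypopnea")

`%||%` <- function(a, b) if (is.null(a)) b else a

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Runs of TRUE in a logical vector as (start, end) index pairs (inclusive).
.runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & !is.na(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

# Deterministic sub-seed derivation; keeps results < 2^31 and reproducible.
.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + as.numeric(k) * 7919) %%
               2147483629)
}

# Stable small integer hash of a string (for per-subject oracle noise).
.hashString <- function(s) {
  v <- utf8ToInt(s)
  as.integer(sum(v * 31 ^ (seq_along(v) %% 7)) %% 2147483629)
}

# Centered moving average with edge-value padding (no NA at the borders).
.movavg <- function(x, n) {
  if (n <= 1) return(x)
  half <- floor(n / 2)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], n - half - 1))
  as.numeric(stats::filter(xp, rep(1 / n, n), sides = 1))[n:(n - 1 + length(x))]
}

.isScalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Validate a two-column matrix of half-open [start, end) intervals in seconds.
.checkIntervals <- function(m, what = "interval") {
  if (is.null(m) || nrow(m) == 0) return(TRUE)
  if (ncol(m) != 2) return(sprintf("%s matrix must have two columns", what))
  if (any(m < 0)) return(sprintf("%s times must be non-negative", what))
  if (any(m[, 2] <= m[, 1])) {
    return(sprintf("%s intervals must have positive length ([start, end))", what))
  }
  if (is.unsorted(m[, 1])) return(sprintf("%s intervals must be sorted by start", what))
  TRUE
}

# md5 of an R object via its canonical JSON rendering (provenance hashes).
.configHash <- function(obj) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, force = TRUE,
                              null = "null"), tf)
  unname(tools::md5sum(tf))
}

.provenance <- function(config = NULL, seed = NULL) {
  list(package = "somnage",
       version = as.character(utils::packageVersion("somnage")),
       config_hash = if (is.null(config)) NA_character_ else .configHash(config),
       seed = seed)
}
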