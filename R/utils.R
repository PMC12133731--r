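# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library functions never perturb
# the global stream. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a parent seed and a purpose tag, so that e.g.
# adding covariates to a simulation never perturbs the coordinate draw.
# Kept within the positive 32-bit integer range.
derive_seed <- function(seed, purpose) {
  if (is.null(seed)) return(NULL)
  offsets <- c(layout = 11L, covariates = 23L, noise = 37L, missing = 53L,
               surface = 71L, field = 89L, permute = 101L)
  off <- offsets[[purpose]]
  ((as.integer(seed) %% 1000003L) * 211L + off) %% 2147483563L
}

stop_gtwr <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "gtwr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

warn_gtwr <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  warning(structure(class = c(class, "gtwr_warning", "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
}

check_numeric_matrix_coords <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) < 2L)
    stop_gtwr("invalid_config", "coords must have two columns (u, v)")
  storage.mode(coords) <- "double"
  if (any(!is.finite(coords)))
    stop_gtwr("invalid_config", "coords contain non-finite values")
  coords[, 1:2, drop = FALSE]
}
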