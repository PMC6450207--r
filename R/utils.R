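## Internal helpers shared across modules.

#' @importFrom stats rnorm runif rbinom quantile sd var qnorm pnorm setNames
#' @importFrom utils head read.csv write.csv
NULL

# Split `total` days into `k` contiguous periods as equal as possible;
# remainder days are appended to the final period.
split_days <- function(total, k) {
  stopifnot(total >= k, k >= 1)
  lens <- rep(total %/% k, k)
  lens[k] <- lens[k] + total %% k
  lens
}

# Deterministic per-run seed derived from a master seed and run labels.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(master, ...) {
  labels <- paste(c(master, ...), collapse = "|")
  codes <- utf8ToInt(labels)
  h <- as.double(master %% 1048576L)
  for (cc in codes) h <- (h * 131 + cc) %% 2147483629
  as.integer(h + 1)
}

# Run `expr` under a temporary RNG state seeded with `seed` (if non-NULL),
# restoring the caller's stream afterwards.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cell index (1-based) containing planar coordinate v (metres), half-open
# intervals [i*cs, (i+1)*cs).
coord_to_cell <- function(v, cell_size) floor(v / cell_size) + 1L

cell_center <- function(i, cell_size) (i - 0.5) * cell_size
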