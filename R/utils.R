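# Internal helpers: seeding, clipping, id formatting.

# Derive a reproducible sub-stream seed from a master seed and a hierarchy of
# small integer labels (subject, visit, scan). Lehmer-style mixing mod
# 2^31 - 149; multiplier kept small so the product stays exactly
# representable in doubles.
derive_seed <- function(master, ...) {
  m <- 2147483499
  h <- as.numeric(master) %% m
  for (v in c(...)) {
    h <- (h * 69069 + as.numeric(v) %% m + 1) %% m
  }
  as.integer(h)
}

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Canonical textual id of one scan, used in score tables and reports.
format_scan_id <- function(subject_id, visit_id, scan_id) {
  sprintf("%s_v%d_s%d", subject_id, as.integer(visit_id), as.integer(scan_id))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
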