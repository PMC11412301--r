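# Shared internal helpers.

#' Muscle channel order
#'
#' Fixed order of the eight surface-EMG channels used throughout the package:
#' biceps brachii long head, triceps brachii lateral head, anterior deltoid,
#' medial deltoid, posterior deltoid, pectoralis major, middle trapezius,
#' upper trapezius.
#'
#' @return Character vector of length 8.
#' @export
muscle_names <- function() {
  c("bic", "tri", "antdel", "meddel", "posdel", "pec", "trapm", "trapu")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated-normal draw by rejection; floor only (upper tail open).
rtruncnorm_floor <- function(n, mean, sd, floor) {
  if (sd == 0) return(rep(pmax(mean, floor), n))
  out <- rnorm(n, mean, sd)
  bad <- out < floor
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < floor
  }
  out
}

# Smoothstep ramp from 0 to 1 over [t0, t1]; clamped outside.
smoothstep <- function(t, t0, t1) {
  x <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  x * x * (3 - 2 * x)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
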