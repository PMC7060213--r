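#' Derive a stage seed from a master seed
#'
#' All stochastic stages draw their seed from one master seed plus a stage
#' offset, so that a single `--seed` reproduces every table bit-identically
#' while stages stay statistically independent.
#'
#' @param master integer master seed.
#' @param stage integer stage offset (>= 0).
#' @return an integer seed < 2^31.
#' @export
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 10007 + as.numeric(stage) * 97 + 1) %% 2147483647)
}

# run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  force(expr)
}

#' Analytic-signal envelope via the FFT
#'
#' Returns the complex analytic signal of a real vector (negative frequencies
#' zeroed, positive doubled). `Mod(analytic_signal(x))` is the Hilbert
#' envelope.
#'
#' @param x numeric vector.
#' @return complex vector, same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(f * h, inverse = TRUE) / n
}

msg_stage <- function(verbose, stage, ...) {
  if (isTRUE(verbose)) message(sprintf("[%s] %s", stage, paste0(...)))
}
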