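#' Seeded deterministic random stream
#'
#' A minimal Lehmer (Park-Miller "MINSTD") multiplicative congruential
#' generator, `state <- (16807 * state) mod (2^31 - 1)`, carried in double
#' precision (exact: 16807 * (2^31 - 2) < 2^53). All synthetic-data
#' generators in the package draw from this stream rather than from R's
#' session RNG, so generated ligands, libraries and complexes are
#' bit-identical across platforms and never perturb (or depend on)
#' `set.seed()` state in the calling session.
#'
#' @param seed integer seed; any finite value is folded into \[1, 2^31 - 2].
#' @return an environment with methods `unif(n)` (doubles in (0,1)),
#'   `int(n, max)` (integers in 1..max), `norm(n)` (standard normals via
#'   Box-Muller), and `perm(n)` (a random permutation by Fisher-Yates).
#' @examples
#' r <- kp_rng(42)
#' r$unif(3)
#' kp_rng(42)$unif(3)  # identical
#' @export
kp_rng <- function(seed) {
  m <- 2147483647
  state <- (abs(as.numeric(seed)) %% (m - 1)) + 1
  nxt <- function() {
    state <<- (16807 * state) %% m
    state / m
  }
  self <- new.env(parent = emptyenv())
  self$unif <- function(n = 1L) vapply(seq_len(n), function(i) nxt(), 0)
  self$int <- function(n = 1L, max) {
    pmin(max, floor(self$unif(n) * max) + 1L)
  }
  self$norm <- function(n = 1L) {
    # Box-Muller; draws pairs, discards the spare for simplicity
    u1 <- self$unif(n)
    u2 <- self$unif(n)
    sqrt(-2 * log(u1)) * cos(2 * pi * u2)
  }
  self$perm <- function(n) {
    p <- seq_len(n)
    if (n < 2L) return(p)
    for (i in seq(n, 2L)) {
      j <- self$int(1L, i)
      tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
    }
    p
  }
  self
}
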