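#' @keywords internal
"_PACKAGE"

# Modulus and multiplier of the MINSTD linear congruential generator.
# h < 2^31 and m < 2^16 keep h * m below 2^53, so the chain is exact in
# double arithmetic.
.seed_mod <- 2147483647
.seed_mult <- 48271

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from integer seeds. Sub-seeds for
#' nested tasks (collections in a suite, refits within a simulation, runs in
#' a manifest) are derived by chaining the master seed with a sequence of
#' components through a fixed integer hash, so results do not depend on the
#' order in which tasks happen to be executed.
#'
#' @param master integer master seed.
#' @param ... components (integers or strings) identifying the sub-task.
#' @return An integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(42, "collection", 3)
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- (abs(master) %% .seed_mod)
  for (part in list(...)) {
    codes <- if (is.character(part)) {
      unlist(lapply(part, utf8ToInt), use.names = FALSE)
    } else {
      as.numeric(part) %% .seed_mod
    }
    for (x in codes) {
      h <- (h * .seed_mult + x + 1) %% .seed_mod
    }
  }
  as.integer(h %% (.seed_mod - 2) + 1)
}

# Vectorised variant over integer component columns; `parts` is a list of
# equal-length integer vectors. Used for run manifests.
derive_seed_vec <- function(master, parts) {
  h <- rep((abs(master) %% .seed_mod), length(parts[[1L]]))
  for (x in parts) {
    h <- (h * .seed_mult + (as.numeric(x) %% .seed_mod) + 1) %% .seed_mod
  }
  as.integer(h %% (.seed_mod - 2) + 1)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ceiling/floor guarded against binary representation of fractions such as
# 0.95 * 20 evaluating to 19.000000000000004
ceil_frac <- function(x) as.integer(ceiling(x - 1e-9))
floor_frac <- function(x) as.integer(floor(x + 1e-9))

#' Smallest-denominator rational approximation
#'
#' Converts a target prevalence into a reduced fraction a/b via the
#' continued-fraction expansion, so that exact-ratio subsetting can be done
#' in integer arithmetic.
#'
#' @param p a number in (0, 1).
#' @param tol absolute tolerance.
#' @param max_denom largest denominator considered.
#' @return integer vector `c(num, den)` with `num/den` within `tol` of `p`.
#' @keywords internal
rational_approx <- function(p, tol = 1e-9, max_denom = 1000000L) {
  stopifnot(p > 0, p < 1)
  h0 <- 0; k0 <- 1; h1 <- 1; k1 <- 0
  x <- p
  repeat {
    a <- floor(x)
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (k2 > max_denom) break
    h0 <- h1; k0 <- k1; h1 <- h2; k1 <- k2
    if (abs(h1 / k1 - p) < tol) break
    frac <- x - a
    if (frac < tol) break
    x <- 1 / frac
  }
  if (abs(h1 / k1 - p) >= tol) {
    stop("no exact rational representation of prevalence ", p,
         " with denominator <= ", max_denom)
  }
  c(num = as.integer(h1), den = as.integer(k1))
}
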