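#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider complete replace_na
NULL

# classed abort helper so callers can condition on error families
ls_abort <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "loopshift_error"), ...)
}

# standard atomic masses (amu) for the elements found in protein heavy-atom
# and hydrogen records
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  P = 30.974, S = 32.06, SE = 78.971, FE = 55.845
)

# infer the element from a PDB atom name when the element column is absent:
# strip digits/primes, take the leading letter (protein context, so "CA" is
# a carbon, not calcium)
infer_element <- function(atom_name) {
  stripped <- gsub("[0-9']", "", trimws(atom_name))
  el <- toupper(substr(stripped, 1, 1))
  el[el == ""] <- "C"
  el
}

element_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Seed-derived sub-seeds
#'
#' Fans one base seed out into a reproducible sequence of 32-bit sub-seeds
#' (used so each replica / rule / simulation draws from an independent,
#' documented stream).
#'
#' @param seed Base integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  # affine hash in 31-bit arithmetic, deterministic and platform independent
  a <- 48271
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% (m - 1)) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (a * x) %% m
    out[i] <- x
  }
  as.integer(out)
}
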