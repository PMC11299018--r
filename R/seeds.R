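# Deterministic substream derivation.  A master seed expands into a
# prefix-stable sequence of 31-bit child seeds: asking for more seeds never
# changes the ones already issued, so extending a run with extra replicates
# leaves earlier replicates bit-identical.

#' Derive child seeds from a master seed
#'
#' Seeds are drawn from a dedicated RNG stream keyed by `master_seed`; the
#' caller's RNG state is saved and restored, so calling this function is
#' invisible to surrounding code.  The sequence is prefix-stable in `n`.
#'
#' @param master_seed single integer-valued number.
#' @param n number of child seeds required.
#' @return integer vector of length `n`, each in `[1, 2^31 - 1]`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed),
            master_seed == round(master_seed),
            length(n) == 1L, n >= 0)
  if (n == 0) return(integer(0))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master_seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max, n, replace = TRUE)
}
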