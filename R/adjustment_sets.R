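# The adjustment-set library: which covariates enter the sampling model
# (inverse odds weighting) or the stratified outcome model.

#' Adjustment set
#'
#' A named, ordered subset of covariate labels together with a referent tag
#' that determines the denominator of its relative-SE comparison:
#' * `"self"` — the set is its own referent (ratio reported as blank);
#' * `"alone"` — compared against the empty (crude) set;
#' * `"plus_z111"` — compared against the minimally sufficient set
#'   (`Z111` alone).
#'
#' @param name display name, e.g. `"Z100+Z111"` or `"Z110 alone"`.
#' @param members character vector of covariate labels, possibly empty.
#' @param referent one of `"self"`, `"alone"`, `"plus_z111"`.
#' @return object of class `adjustment_set`.
#' @export
adjustment_set <- function(name, members = character(0),
                           referent = c("self", "alone", "plus_z111")) {
  referent <- match.arg(referent)
  stopifnot(is.character(name), length(name) == 1L, is.character(members))
  if (anyDuplicated(members)) stop("adjustment set members must be unique")
  structure(list(name = name, members = members, referent = referent),
            class = "adjustment_set")
}

#' @export
print.adjustment_set <- function(x, ...) {
  cat(sprintf("<adjustment_set '%s'> {%s} referent=%s\n", x$name,
              paste(x$members, collapse = ", "), x$referent))
  invisible(x)
}

#' The standard 12-set adjustment library
#'
#' In row order: the empty set (crude); `Z111` alone (the minimally
#' sufficient set); each of the five other covariates added to `Z111`; and
#' each of the five other covariates alone (probing bias amplification when
#' the necessary EMM is omitted).
#'
#' @param others labels of the non-`Z111` covariates, in display order.
#' @return list of 12 [adjustment_set()] objects.
#' @export
standard_adjustment_sets <- function(others = c("Z000", "Z010", "Z011",
                                                "Z100", "Z110")) {
  sets <- list(
    adjustment_set("empty", character(0), "self"),
    adjustment_set("Z111 alone", "Z111", "self"))
  for (z in others)
    sets <- c(sets, list(adjustment_set(paste0(z, "+Z111"), c(z, "Z111"),
                                        "plus_z111")))
  for (z in others)
    sets <- c(sets, list(adjustment_set(paste(z, "alone"), z, "alone")))
  sets
}

# Name of the referent set for relative-SE ratios.
referent_name <- function(set) {
  switch(set$referent,
         self = set$name,
         alone = "empty",
         plus_z111 = "Z111 alone")
}

# Look an adjustment set up by name within a list.
find_set <- function(sets, name) {
  for (s in sets) if (s$name == name) return(s)
  NULL
}
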