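`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stable per-entity seed derived from a run seed
#'
#' Generators draw each entity (compound-condition arm, disease cohort, null
#' stratum) from its own stream so that adding entities never perturbs the
#' draws of existing ones. Offsets are kept inside 32-bit integer range.
#'
#' @param seed integer run seed.
#' @param offset stable non-negative integer offset for the entity.
#' @return an integer seed.
#' @keywords internal
entity_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

#' Count, for each value, how many elements of a sorted vector are >= it
#'
#' Tie-exact via findInterval on the left-open grid: #{x >= v} = N - #{x < v}.
#' @keywords internal
count_ge <- function(values, sorted_null) {
  length(sorted_null) - findInterval(values, sorted_null, left.open = TRUE)
}

stop_sigrev <- function(msg, class) {
  stop(structure(class = c(class, "sigrev_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
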