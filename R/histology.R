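#' NAFLD activity score (NAS)
#'
#' NAS = steatosis (0-3) + hepatocyte ballooning (0-2) + lobular
#' inflammation (0-3), giving a 0-8 scale. Fibrosis stage and portal
#' inflammation are staged separately and never enter the sum. Group-mean
#' mode (the default) accepts fractional components, as published summary
#' tables report fractional means; per-animal mode additionally requires
#' integer components.
#'
#' @param steatosis,ballooning,lobular_inflammation numeric vectors of
#'   component scores (recycled to a common length).
#' @param per_animal logical; TRUE enforces integer components.
#' @return numeric NAS vector in `[0, 8]`.
#' @export
nafld_activity_score <- function(steatosis, ballooning, lobular_inflammation,
                                 per_animal = FALSE) {
  check_component <- function(x, name, hi) {
    if (any(is.na(x)) || any(x < 0) || any(x > hi))
      stop_sigrev(sprintf("%s out of range [0, %d]", name, hi),
                  "sigrev_validation_error")
    if (per_animal && any(x != round(x)))
      stop_sigrev(sprintf("%s must be integer in per-animal mode", name),
                  "sigrev_validation_error")
  }
  check_component(steatosis, "steatosis", 3L)
  check_component(ballooning, "ballooning", 2L)
  check_component(lobular_inflammation, "lobular_inflammation", 3L)
  steatosis + ballooning + lobular_inflammation
}

#' Group summary: mean, SEM and n
#'
#' SEM is the sample standard deviation (n - 1 denominator) divided by
#' `sqrt(n)`; with fewer than two values it is flagged unavailable (`NA`).
#'
#' @param x numeric vector of per-animal values.
#' @return list with `mean`, `sem`, `n`.
#' @export
group_summary <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) stop_sigrev("no values to summarise", "sigrev_input_error")
  list(mean = mean(x),
       sem = if (n >= 2L) stats::sd(x) / sqrt(n) else NA_real_,
       n = n)
}

#' Per-group NAS summaries from a histology score table
#'
#' @param scores data.frame with columns `steatosis`, `ballooning`,
#'   `lobular_inflammation` and optionally a grouping column.
#' @param by name of the grouping column (NULL summarises all rows as one
#'   group).
#' @param per_animal passed to [nafld_activity_score()].
#' @return data.frame with one row per group: group, n, nas_mean, nas_sem.
#' @export
nas_summary <- function(scores, by = NULL, per_animal = TRUE) {
  nas <- nafld_activity_score(scores$steatosis, scores$ballooning,
                              scores$lobular_inflammation, per_animal = per_animal)
  groups <- if (is.null(by)) rep("all", nrow(scores)) else as.character(scores[[by]])
  out <- lapply(split(nas, groups), group_summary)
  data.frame(group = names(out),
             n = vapply(out, `[[`, numeric(1), "n"),
             nas_mean = vapply(out, `[[`, numeric(1), "mean"),
             nas_sem = vapply(out, `[[`, numeric(1), "sem"),
             stringsAsFactors = FALSE, row.names = NULL)
}
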