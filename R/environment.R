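#' Milk energy yield
#'
#' Combines the three milk yield traits (kilograms) into a single energy
#' yield value, `0.802*milk + 38.4*fat + 23.6*protein`.  The weights are
#' the standard energy contents of the milk carrier and of fat and protein.
#'
#' @param milk_kg,fat_kg,protein_kg Non-negative yields in kg (vectorized).
#' @return Numeric energy yield.
#' @examples
#' compute_energy_yield(25, 1.0, 0.85)
#' @export
compute_energy_yield <- function(milk_kg, fat_kg, protein_kg) {
  if (any(milk_kg < 0, na.rm = TRUE) || any(fat_kg < 0, na.rm = TRUE) ||
      any(protein_kg < 0, na.rm = TRUE)) {
    abort("yields must be non-negative.", class = "reactnorm_domain_error")
  }
  0.802 * milk_kg + 38.4 * fat_kg + 23.6 * protein_kg
}

#' Continuous environmental descriptor per herd-test-day
#'
#' The environment of a herd-test-day is described by its mean performance:
#' the within-herd-test-day mean of record-level milk energy yield (columns
#' `milk_kg`, `fat_kg`, `protein_kg`), or of a single `yield` column when
#' the three components are not present.  Raw levels are standardized over
#' herd-test-day units (each environment weighted equally) to mean 0 and
#' SD 1, so positive values are superior environments.
#'
#' @param records Data frame with a herd-test-day id column and yield
#'   column(s).
#' @param htd_col Name of the herd-test-day id column.
#' @return Tibble with columns `htd`, `raw`, `env` (standardized value).
#' @examples
#' recs <- tibble::tibble(htd = c("a", "a", "b"),
#'                        milk_kg = c(24, 26, 30), fat_kg = 1, protein_kg = 0.8)
#' compute_environment_descriptor(recs)
#' @export
compute_environment_descriptor <- function(records, htd_col = "htd") {
  records <- as_tibble(records)
  if (!htd_col %in% names(records)) {
    abort(paste0("column `", htd_col, "` not found."), class = "reactnorm_domain_error")
  }
  has3 <- all(c("milk_kg", "fat_kg", "protein_kg") %in% names(records))
  if (!has3 && !"yield" %in% names(records)) {
    abort("records need `milk_kg`/`fat_kg`/`protein_kg` or a `yield` column.",
          class = "reactnorm_domain_error")
  }
  level <- if (has3) {
    compute_energy_yield(records$milk_kg, records$fat_kg, records$protein_kg)
  } else {
    records$yield
  }
  if (anyNA(level)) {
    abort("records with missing yields cannot enter the descriptor.",
          class = "reactnorm_domain_error")
  }
  out <- tibble(htd = records[[htd_col]], level = level) %>%
    group_by(.data$htd) %>%
    summarise(raw = mean(.data$level), .groups = "drop")
  s <- sd(out$raw)
  if (!is.finite(s) || s == 0) {
    abort("herd-test-day levels are constant; the descriptor is undefined.",
          class = "reactnorm_domain_error")
  }
  out$env <- (out$raw - mean(out$raw)) / s
  out
}

#' Assign residual-variance classes by environment decile
#'
#' Orders records by their environment value and splits them into
#' `n_classes` contiguous groups of (as near as possible) equal size; group
#' sizes differ by at most one, with any remainder going to the lowest
#' classes.  Ties in the environment value are broken by stable record
#' order.
#'
#' @param records Data frame carrying the environment value.
#' @param n_classes Number of classes (default 10, i.e. deciles).
#' @param env_col Name of the environment column.
#' @return Integer vector of class labels (1 = poorest environments), in
#'   the original record order.
#' @examples
#' assign_residual_classes(tibble::tibble(env = rnorm(25)), n_classes = 5)
#' @export
assign_residual_classes <- function(records, n_classes = 10, env_col = "env") {
  records <- as_tibble(records)
  n <- nrow(records)
  if (n_classes < 1) abort("`n_classes` must be >= 1.", class = "reactnorm_domain_error")
  if (n < n_classes) {
    abort("fewer records than residual classes.", class = "reactnorm_domain_error")
  }
  base <- n %/% n_classes
  extra <- n %% n_classes
  sizes <- rep(base, n_classes) + c(rep(1L, extra), rep(0L, n_classes - extra))
  ord <- order(records[[env_col]])  # stable for ties
  cls <- integer(n)
  cls[ord] <- rep(seq_len(n_classes), sizes)
  cls
}
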