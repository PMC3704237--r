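#' Numerator relationship matrix from a pedigree (tabular method)
#'
#' Builds the additive (numerator) relationship matrix A over the pedigree
#' closure of the requested ids — the ids themselves plus all their
#' ancestors — by the tabular recursion: after sorting parents before
#' offspring, \eqn{a_{ii} = 1 + a_{sire(i),dam(i)}/2} and
#' \eqn{a_{ij} = (a_{j,sire(i)} + a_{j,dam(i)})/2} for previously processed
#' `j`, with unknown parents contributing 0 (founders are treated as
#' unrelated and non-inbred).  The result is restricted to the requested
#' ids.
#'
#' @param pedigree Data frame with columns `id`, `sire`, `dam`; `"0"`,
#'   `""` or `NA` denote an unknown parent.  Parents that appear only in
#'   the `sire`/`dam` columns are added as founders.
#' @param ids Character vector of ids to return (default: all pedigree
#'   ids), in the requested order.
#' @return Symmetric numeric matrix with `ids` as dimnames.
#' @examples
#' ped <- tibble::tibble(id = c("f1", "f2", "kid"),
#'                       sire = c("0", "0", "f1"), dam = c("0", "0", "f2"))
#' build_numerator_relationship(ped)["kid", "f1"]
#' @export
build_numerator_relationship <- function(pedigree, ids = NULL) {
  ped <- as_tibble(pedigree)
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- NA_character_
    x
  }
  ped <- tibble(id = as.character(ped$id), sire = norm(ped$sire), dam = norm(ped$dam))
  if (anyDuplicated(ped$id)) {
    abort("duplicated ids in pedigree.", class = "reactnorm_pedigree_error")
  }
  if (is.null(ids)) ids <- ped$id
  ids <- as.character(ids)
  if (!all(ids %in% ped$id)) {
    abort(paste0("ids not in pedigree: ",
                 paste(head(setdiff(ids, ped$id), 5), collapse = ", ")),
          class = "reactnorm_pedigree_error")
  }

  # implicit founders: parents never listed as individuals
  known <- ped$id
  implied <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), known)
  if (length(implied)) {
    ped <- bind_rows(tibble(id = implied, sire = NA_character_, dam = NA_character_), ped)
  }

  # restrict to the closure of the requested ids
  keep <- character(0)
  frontier <- ids
  sire_of <- setNames(ped$sire, ped$id)
  dam_of <- setNames(ped$dam, ped$id)
  while (length(frontier)) {
    keep <- union(keep, frontier)
    parents <- stats::na.omit(unique(c(sire_of[frontier], dam_of[frontier])))
    frontier <- setdiff(parents, keep)
  }
  ped <- ped[ped$id %in% keep, , drop = FALSE]

  # topological sort (Kahn); cycles detected when no progress is possible
  n <- nrow(ped)
  order_ids <- character(0)
  placed <- logical(n)
  names(placed) <- ped$id
  repeat {
    ready <- !placed &
      (is.na(sire_of[ped$id]) | placed[sire_of[ped$id]] %in% TRUE) &
      (is.na(dam_of[ped$id]) | placed[dam_of[ped$id]] %in% TRUE)
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) {
      if (all(placed)) break
      abort("pedigree contains a cycle (an individual is its own ancestor).",
            class = "reactnorm_pedigree_error")
    }
    order_ids <- c(order_ids, ped$id[ready])
    placed[ped$id[ready]] <- TRUE
  }

  A <- matrix(0, n, n, dimnames = list(order_ids, order_ids))
  idx <- setNames(seq_len(n), order_ids)
  for (i in seq_len(n)) {
    id <- order_ids[i]
    s <- sire_of[[id]]; d <- dam_of[[id]]
    si <- if (!is.na(s)) idx[[s]] else 0L
    di <- if (!is.na(d)) idx[[d]] else 0L
    if (i > 1) {
      prev <- seq_len(i - 1)
      row_s <- if (si > 0) A[prev, si] else numeric(i - 1)
      row_d <- if (di > 0) A[prev, di] else numeric(i - 1)
      A[prev, i] <- A[i, prev] <- (row_s + row_d) / 2
    }
    A[i, i] <- 1 + if (si > 0 && di > 0) A[si, di] / 2 else 0
  }
  A[ids, ids, drop = FALSE]
}
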