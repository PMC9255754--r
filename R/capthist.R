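#' Assemble a validated capture history
#'
#' A capture history records, for one trapping session, which individuals
#' were caught in which trap on each occasion.  Multi-catch traps admit at
#' most one record per individual per occasion.
#'
#' @param records A data frame with columns `individual`, `occasion`
#'   (1-based integer), `trap_id`, and optionally `sex` (`"F"`, `"M"` or
#'   `"unknown"`).
#' @param n_occasions Number of occasions in the session.
#' @param session Session label (e.g. the year).
#' @param traps Optional `trap_array`; if given, every `trap_id` must occur
#'   in it.
#' @return A tibble of class `capture_history` with attributes
#'   `n_occasions` and `session`.
#' @export
capture_history <- function(records, n_occasions, session = "session1",
                            traps = NULL) {
  if (!is_count(n_occasions)) {
    stop("`n_occasions` must be a positive integer", call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  need <- c("individual", "occasion", "trap_id")
  if (!all(need %in% names(records))) {
    stop("capture records need columns individual, occasion, trap_id",
         call. = FALSE)
  }
  if (!"sex" %in% names(records)) records$sex <- "unknown"
  records$individual <- as.character(records$individual)
  records$trap_id <- as.character(records$trap_id)
  records$sex <- as.character(records$sex)
  if (nrow(records) > 0) {
    if (!all(records$occasion == round(records$occasion)) ||
        any(records$occasion < 1) || any(records$occasion > n_occasions)) {
      stop("occasions must be integers in 1..n_occasions", call. = FALSE)
    }
    records$occasion <- as.integer(records$occasion)
    if (anyDuplicated(records[, c("individual", "occasion")])) {
      stop("multi-catch data admit at most one record per individual per occasion",
           call. = FALSE)
    }
    if (!all(records$sex %in% c("F", "M", "unknown"))) {
      stop("sex must be one of \"F\", \"M\", \"unknown\"", call. = FALSE)
    }
    bad_sex <- stats::aggregate(sex ~ individual, records,
                                function(s) length(unique(s)))
    if (any(bad_sex$sex > 1)) {
      stop("an individual cannot carry two different sex labels", call. = FALSE)
    }
    if (!is.null(traps) && !all(records$trap_id %in% traps$trap_id)) {
      stop("capture records refer to trap ids absent from the trap array",
           call. = FALSE)
    }
  } else {
    records <- tibble::tibble(individual = character(), occasion = integer(),
                              trap_id = character(), sex = character())
  }
  records <- dplyr::arrange(records, .data$individual, .data$occasion)
  structure(records,
            n_occasions = as.integer(n_occasions),
            session = session,
            class = c("capture_history", class(tibble::tibble())))
}

#' Number of occasions in a capture history
#' @param ch A `capture_history`.
#' @return Integer count of occasions.
#' @export
n_occasions <- function(ch) attr(ch, "n_occasions")

#' Number of distinct individuals in a capture history
#' @param ch A `capture_history`.
#' @return Integer count of individuals.
#' @export
n_individuals <- function(ch) length(unique(ch$individual))

#' Count spatial recaptures
#'
#' A spatial recapture is a recapture at a trap other than one the
#' individual was already caught in; these movements carry the information
#' about the spatial scale `sigma`, so fits with very few of them are
#' flagged as unstable.
#'
#' @param ch A `capture_history`.
#' @return Integer: the summed count over individuals of distinct traps
#'   used minus one.
#' @export
n_spatial_recaptures <- function(ch) {
  if (nrow(ch) == 0) return(0L)
  moves <- dplyr::summarise(dplyr::group_by(ch, .data$individual),
                            m = dplyr::n_distinct(.data$trap_id) - 1L)
  sum(moves$m)
}

# n x S matrix of trap indices (0 = not caught), plus class codes
capthist_matrices <- function(ch, traps) {
  S <- n_occasions(ch)
  ids <- unique(ch$individual)
  n <- length(ids)
  caps <- matrix(0L, nrow = n, ncol = S)
  if (n > 0) {
    ii <- match(ch$individual, ids)
    kk <- match(ch$trap_id, traps$trap_id)
    if (anyNA(kk)) stop("capture records refer to unknown traps", call. = FALSE)
    caps[cbind(ii, ch$occasion)] <- kk
  }
  sex <- if (n > 0) {
    first <- ch[!duplicated(ch$individual), , drop = FALSE]
    sx <- first$sex[match(ids, first$individual)]
    c(F = 1L, M = 2L, unknown = 0L)[sx]
  } else integer(0)
  list(caps = caps, sex = unname(sex), ids = ids, S = S)
}
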