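fmt_num <- function(x) formatC(signif(x, 6), format = "g", digits = 6)

parse_delimited <- function(path, n_fields, what, skip_header = TRUE) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  toks <- strsplit(trimws(lines[keep]), "[,\t ]+")
  if (length(toks) == 0) {
    stop("no data rows in ", what, " file ", path, call. = FALSE)
  }
  # an optional plain header row of field names
  if (skip_header && all(is.na(suppressWarnings(as.numeric(toks[[1]])))) &&
      length(toks) > 1) {
    keep <- keep[-1]; toks <- toks[-1]
  }
  bad <- which(lengths(toks) != n_fields)
  if (length(bad)) {
    stop(sprintf("malformed %s row at line %d of %s (expected %d fields)",
                 what, keep[bad[1]], path, n_fields), call. = FALSE)
  }
  list(toks = toks, lines = keep)
}

#' Read a trap layout file
#'
#' Plain-text, whitespace- or comma-delimited, three columns
#' (`trap_id x y`, metres); lines starting with `#` are comments.
#'
#' @param path File path.
#' @param detector Detector kind to attach.
#' @return A `trap_array`.
#' @export
read_traps <- function(path, detector = "multi_catch") {
  p <- parse_delimited(path, 3L, "trap")
  df <- tibble::tibble(
    trap_id = purrr::map_chr(p$toks, 1),
    x = suppressWarnings(as.numeric(purrr::map_chr(p$toks, 2))),
    y = suppressWarnings(as.numeric(purrr::map_chr(p$toks, 3)))
  )
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad)) {
    stop(sprintf("non-numeric coordinate at line %d of %s",
                 p$lines[bad[1]], path), call. = FALSE)
  }
  if (anyDuplicated(df$trap_id)) {
    stop("duplicate trap ids in ", path, call. = FALSE)
  }
  new_trap_array(df, detector = detector)
}

#' Write a trap layout file
#'
#' @param traps A `trap_array`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_traps <- function(traps, path) {
  traps <- traps[order(traps$trap_id), ]
  lines <- c("# trap layout: trap_id x y (metres)",
             paste(traps$trap_id, fmt_num(traps$x), fmt_num(traps$y)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a capture-history file
#'
#' Delimited text with columns `session individual occasion trap_id sex`,
#' occasions 1-based.  Every `trap_id` must exist in the companion trap
#' array; duplicate (individual, occasion) records are rejected.
#'
#' @param path File path.
#' @param traps The companion `trap_array`.
#' @param n_occasions Occasions per session; defaults to the largest
#'   occasion index present.
#' @return A [capture_history()] if the file holds a single session,
#'   otherwise a named list of them.
#' @export
read_capthist <- function(path, traps, n_occasions = NULL) {
  p <- parse_delimited(path, 5L, "capture")
  df <- tibble::tibble(
    session = purrr::map_chr(p$toks, 1),
    individual = purrr::map_chr(p$toks, 2),
    occasion = suppressWarnings(as.numeric(purrr::map_chr(p$toks, 3))),
    trap_id = purrr::map_chr(p$toks, 4),
    sex = purrr::map_chr(p$toks, 5)
  )
  bad <- which(!is.finite(df$occasion) | df$occasion < 1 |
                 df$occasion != round(df$occasion))
  if (length(bad)) {
    stop(sprintf("invalid occasion at line %d of %s", p$lines[bad[1]], path),
         call. = FALSE)
  }
  bad <- which(!df$trap_id %in% traps$trap_id)
  if (length(bad)) {
    stop(sprintf("unknown trap id '%s' at line %d of %s",
                 df$trap_id[bad[1]], p$lines[bad[1]], path), call. = FALSE)
  }
  if (is.null(n_occasions)) n_occasions <- max(df$occasion)
  out <- lapply(split(df, df$session), function(one) {
    capture_history(one[, c("individual", "occasion", "trap_id", "sex")],
                    n_occasions, session = one$session[1], traps = traps)
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Write a capture-history file
#'
#' @param ch A [capture_history()] or list of them.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_capthist <- function(ch, path) {
  if (inherits(ch, "capture_history")) ch <- list(ch)
  rows <- purrr::map(ch, function(one) {
    if (nrow(one) == 0) return(character(0))
    paste(attr(one, "session"), one$individual, one$occasion, one$trap_id,
          one$sex)
  })
  writeLines(c("# capture records: session individual occasion trap_id sex",
               unlist(rows)), path)
  invisible(path)
}

#' Write a habitat mask file
#'
#' Same dialect as the trap file: `x y` columns with the cell area recorded
#' in a metadata comment.
#'
#' @param mask A `habitat_mask`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  meta <- sprintf("# habitat mask: cell_area_ha %s spacing %s buffer %s",
                  fmt_num(attr(mask, "cell_area_ha")),
                  fmt_num(attr(mask, "spacing")),
                  fmt_num(attr(mask, "buffer")))
  writeLines(c(meta, "# x y (metres)",
               paste(fmt_num(mask$x), fmt_num(mask$y))), path)
  invisible(path)
}

#' Write a simulation truth ledger
#'
#' Records the generating parameters and per-session seeds of a synthetic
#' study so downstream recovery analyses can be checked against truth.
#'
#' @param truth The `truth` tibble of a [synth_study()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_truth_ledger <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}

#' Read a simulation truth ledger
#' @param path File path.
#' @return A tibble.
#' @export
read_truth_ledger <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read a design-scenario configuration file
#'
#' Human-editable delimited text describing the scenarios of a design
#' study.  Data columns are `label rule n anchor spacing occasions`
#' (missing fields written as `.`); `occasions` is a semicolon-separated
#' index list such as `1;2;3`.  Header comments `# n_reps: <int>` and
#' `# seed: <int>` carry the replication settings.
#'
#' @param path File path.
#' @return A list with `scenarios` (list of [design_scenario()]),
#'   `n_reps` and `seed` (`NA` if absent from the file).
#' @export
read_scenarios <- function(path) {
  lines <- readLines(path)
  meta <- function(key) {
    m <- grep(sprintf("^#\\s*%s:", key), lines, value = TRUE)
    if (length(m) == 0) return(NA_integer_)
    as.integer(sub(sprintf("^#\\s*%s:\\s*", key), "", m[1]))
  }
  p <- parse_delimited(path, 6L, "scenario", skip_header = FALSE)
  scenarios <- lapply(seq_along(p$toks), function(i) {
    f <- p$toks[[i]]
    num <- function(x) if (x == ".") NULL else as.numeric(x)
    occ <- if (f[6] == ".") NULL else as.integer(strsplit(f[6], ";")[[1]])
    tryCatch(
      design_scenario(f[1], f[2], n = num(f[3]),
                      anchor = if (f[4] == ".") "NW" else f[4],
                      spacing = num(f[5]), occasions = occ),
      error = function(e) {
        stop(sprintf("invalid scenario at line %d of %s: %s",
                     p$lines[i], path, conditionMessage(e)), call. = FALSE)
      })
  })
  list(scenarios = scenarios, n_reps = meta("n_reps"), seed = meta("seed"))
}

#' Write a design-scenario configuration file
#'
#' @param scenarios A list of [design_scenario()] objects.
#' @param path Destination path.
#' @param n_reps,seed Optional replication settings recorded as header
#'   metadata.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(scenarios, path, n_reps = NULL, seed = NULL) {
  hdr <- c("# design scenarios: label rule n anchor spacing occasions",
           if (!is.null(n_reps)) sprintf("# n_reps: %d", as.integer(n_reps)),
           if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)))
  rows <- vapply(scenarios, function(s) {
    dot <- function(x) if (is.null(x)) "." else as.character(x)
    paste(s$label, s$rule, dot(s$n), s$anchor %||% "NW", dot(s$spacing),
          if (is.null(s$occasions)) "." else paste(s$occasions, collapse = ";"))
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
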