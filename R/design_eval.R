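#' Define a trapping-design scenario
#'
#' A scenario names a reduced (or re-spaced) version of a base trapping
#' design: the full grid, an `n x n` contiguous sub-grid, checkerboard
#' half-density thinning, or a re-spaced grid with the same trap count on a
#' wider lattice, combined with the subset of occasions retained.
#'
#' @param label Scenario label used in reports.
#' @param rule One of `"full"`, `"n_by_n"`, `"checkerboard_half"`,
#'   `"respaced"`.
#' @param n Sub-grid side for `"n_by_n"`.
#' @param anchor Sub-grid placement for `"n_by_n"` (see [subgrid()]).
#' @param spacing New lattice spacing (metres) for `"respaced"`.
#' @param occasions Retained occasion indices (1-based); `NULL` keeps all.
#' @param preserve `"count"` (default) or `"extent"` for `"respaced"`:
#'   keep the number of traps and widen the grid, or keep the extent and
#'   thin the lattice.
#' @return A list of class `design_scenario`.
#' @examples
#' design_scenario("9x9", "n_by_n", n = 9)
#' design_scenario("3-day", "full", occasions = 1:3)
#' @export
design_scenario <- function(label, rule = c("full", "n_by_n",
                                            "checkerboard_half", "respaced"),
                            n = NULL, anchor = "NW", spacing = NULL,
                            occasions = NULL, preserve = c("count", "extent")) {
  rule <- match.arg(rule)
  preserve <- match.arg(preserve)
  if (rule == "n_by_n" && !is_count(n %||% 0)) {
    stop("`n_by_n` scenarios need a positive integer `n`", call. = FALSE)
  }
  if (rule == "respaced" &&
      (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)) {
    stop("`respaced` scenarios need a positive `spacing`", call. = FALSE)
  }
  if (!is.null(occasions)) {
    occasions <- as.integer(occasions)
    if (length(occasions) == 0 || any(occasions < 1) ||
        anyDuplicated(occasions)) {
      stop("`occasions` must be distinct positive indices", call. = FALSE)
    }
  }
  structure(list(label = label, rule = rule, n = n, anchor = anchor,
                 spacing = spacing, occasions = occasions,
                 preserve = preserve),
            class = "design_scenario")
}

#' Apply a scenario's trap rule to a base design
#'
#' @param traps The base `trap_array`.
#' @param scenario A `design_scenario`.
#' @return A `trap_array`.
#' @export
scenario_traps <- function(traps, scenario) {
  switch(scenario$rule,
    full = traps,
    n_by_n = subgrid(traps, scenario$n, scenario$anchor),
    checkerboard_half = checkerboard_halve(traps),
    respaced = {
      idx <- lattice_index(traps)
      if (scenario$preserve == "count") {
        build_grid(idx$nx, idx$ny, scenario$spacing,
                   detector = detector_kind(traps))
      } else {
        extent <- (idx$nx - 1L) * idx$spacing
        nn <- floor(extent / scenario$spacing) + 1L
        build_grid(nn, nn, scenario$spacing, detector = detector_kind(traps))
      }
    }
  )
}

#' Subsample a capture history under a design scenario
#'
#' Deletes capture records at removed traps and on removed occasions,
#' renumbers the retained occasions consecutively, and drops individuals
#' left with no records — exactly what re-analysing a reduced design from
#' the full field data entails.  `"respaced"` scenarios have no subsampling
#' interpretation and are rejected.
#'
#' @param ch A [capture_history()].
#' @param traps The base `trap_array` the history was collected on.
#' @param scenario A `design_scenario`.
#' @return A list with elements `capthist` (reduced history) and `traps`
#'   (reduced array).
#' @export
subsample_capthist <- function(ch, traps, scenario) {
  stopifnot(inherits(scenario, "design_scenario"))
  if (scenario$rule == "respaced") {
    stop("a respaced grid cannot be subsampled from field data; use Monte Carlo",
         call. = FALSE)
  }
  new_traps <- scenario_traps(traps, scenario)
  S <- n_occasions(ch)
  occ <- scenario$occasions %||% seq_len(S)
  if (any(occ > S)) {
    stop("scenario retains occasions absent from the capture history",
         call. = FALSE)
  }
  kept <- ch[ch$trap_id %in% new_traps$trap_id & ch$occasion %in% occ, ,
             drop = FALSE]
  kept$occasion <- match(kept$occasion, sort(occ))
  reduced <- capture_history(kept, n_occasions = length(occ),
                             session = attr(ch, "session"), traps = new_traps)
  list(capthist = reduced, traps = new_traps)
}

#' Compare a reduced-design fit with the full-design fit
#'
#' @param full,sub `secr_fit` objects for the same session, or any lists
#'   carrying `D_hat`, `SE_D` and `session` fields.
#' @return A one-row tibble: densities, `difference` (full minus sub),
#'   `abs_difference`, `pct_abs_difference` (percent of the full estimate),
#'   and `within_SE` (is the reduced estimate within one SE of the full
#'   fit?).
#' @export
compare_to_full <- function(full, sub) {
  s1 <- full$session %||% NA; s2 <- sub$session %||% NA
  if (!identical(s1, s2) && !is.na(s1) && !is.na(s2)) {
    stop("fits are for different sessions", call. = FALSE)
  }
  diff <- full$D_hat - sub$D_hat
  tibble::tibble(
    session = s1,
    D_full = full$D_hat, SE_full = full$SE_D, D_sub = sub$D_hat,
    difference = diff,
    abs_difference = abs(diff),
    pct_abs_difference = 100 * abs(diff) / full$D_hat,
    within_SE = abs(diff) <= full$SE_D
  )
}

#' Summarise per-session design comparisons
#'
#' @param records A tibble of rows from [compare_to_full()] (one per
#'   session).
#' @return A one-row tibble: `mean_difference`, `mean_abs_difference`,
#'   `max_abs_difference`, `mean_pct_abs_difference`, and
#'   `replication_rate` (percent of sessions whose reduced estimate fell
#'   within one full-design SE; `NA` if SEs were not supplied).
#' @export
summarize_comparisons <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) < 1) stop("no comparison records", call. = FALSE)
  tibble::tibble(
    n_sessions = nrow(records),
    mean_difference = mean(records$difference),
    mean_abs_difference = mean(abs(records$difference)),
    max_abs_difference = max(abs(records$difference)),
    mean_pct_abs_difference = if ("pct_abs_difference" %in% names(records)) {
      mean(records$pct_abs_difference)
    } else NA_real_,
    replication_rate = if ("within_SE" %in% names(records) &&
                           !anyNA(records$within_SE)) {
      100 * mean(records$within_SE)
    } else NA_real_
  )
}

#' Relative bias of a density estimate
#'
#' @param estimate Estimated density (vectorised).
#' @param truth True density, positive.
#' @return `(estimate - truth) / truth`.
#' @export
relative_bias <- function(estimate, truth) {
  if (any(truth <= 0)) stop("true density must be positive", call. = FALSE)
  (estimate - truth) / truth
}

#' Root mean square error
#'
#' @param estimates Numeric vector of estimates.
#' @param truths True value(s), length 1 or matching `estimates`.
#' @return `sqrt(mean((estimates - truths)^2))`.
#' @export
rmse <- function(estimates, truths) {
  if (length(truths) == 1L) truths <- rep(truths, length(estimates))
  if (length(estimates) != length(truths) || length(estimates) < 1) {
    stop("`estimates` and `truths` must have equal positive length",
         call. = FALSE)
  }
  sqrt(mean((estimates - truths)^2))
}

#' Monte Carlo evaluation of a design scenario
#'
#' Repeatedly simulates a population at the true density, collects captures
#' under the scenario's design, fits the SECR model, and summarises the
#' replicate density estimates as mean relative bias and RMSE.
#' Non-converged or non-identifiable replicates are excluded from the
#' summaries but counted and reported — never silently dropped.
#'
#' @param truth A one-row truth table (columns as in
#'   [study_scenario()]'s `truth`).
#' @param scenario A `design_scenario`.
#' @param n_reps Number of replicates.
#' @param seed Base seed; replicate seeds are derived from it.
#' @param base_traps The base `trap_array` the scenario modifies.
#' @param n_occasions Occasions in the base design (before any occasion
#'   subset).
#' @param detectfn Generator/fitted detection function kind.
#' @param spec A [secr_model()] to fit; defaults to a sex-mixture model of
#'   the generating kind.
#' @param buffer Mask buffer (metres).
#' @param mask_spacing Mask cell side (metres) used for both simulation
#'   region and fitting.
#' @return A list of class `mc_result`: `replicates` (tibble with
#'   `rep`, `seed`, `n`, `D_hat`, `converged`, `rb`), `summary` (tibble
#'   with `mean_RB`, `RMSE`, `n_used`, `n_excluded`), plus the scenario
#'   label and true density.
#' @export
monte_carlo_eval <- function(truth, scenario, n_reps, seed,
                             base_traps = build_grid(10, 10, 9.43),
                             n_occasions = 4L, detectfn = "EX",
                             spec = NULL, buffer = 50, mask_spacing = 10) {
  stopifnot(inherits(scenario, "design_scenario"), n_reps >= 1)
  truth <- tibble::as_tibble(truth)[1, ]
  if (is.null(spec)) {
    spec <- secr_model(detectfn, g0_effects = "sex", sigma_effects = "sex")
  }
  traps <- scenario_traps(base_traps, scenario)
  occ <- scenario$occasions %||% seq_len(n_occasions)
  S <- length(occ)
  mask <- build_mask(traps, buffer, mask_spacing)
  params <- scenario_params(truth, detectfn)
  seeds <- (seed + 7919L * seq_len(n_reps)) %% .Machine$integer.max

  reps <- purrr::map_dfr(seq_len(n_reps), function(j) {
    pop <- simulate_population(truth$D, mask, pmix = truth$pmix,
                               seed = seeds[j])
    ch <- simulate_capthist(pop, traps, S, params,
                            session = scenario$label)
    fit <- fit_secr(ch, traps, mask, spec)
    ok <- fit$convergence && !("non_identifiable" %in% fit$flags)
    det <- fit$detection
    det <- det[det$occasion == 1 & det$state == det$state[1], , drop = FALSE]
    out <- tibble::tibble(rep = j, seed = seeds[j], n = fit$n,
                          D_hat = fit$D_hat, converged = ok,
                          rb = relative_bias(fit$D_hat, truth$D))
    for (r in seq_len(nrow(det))) {
      out[[paste0("g0_", det$class[r])]] <- det$g0[r]
      out[[paste0("sigma_", det$class[r])]] <- det$sigma[r]
    }
    out
  })
  used <- reps[reps$converged, , drop = FALSE]
  if (nrow(used) == 0) {
    stop("no Monte Carlo replicate converged for scenario ", scenario$label,
         call. = FALSE)
  }
  summary <- tibble::tibble(
    scenario = scenario$label, true_D = truth$D,
    mean_RB = mean(used$rb),
    RMSE = rmse(used$D_hat, truth$D),
    sd_RB = stats::sd(used$rb),
    n_used = nrow(used), n_excluded = as.integer(n_reps) - nrow(used)
  )
  structure(list(scenario = scenario$label, true_D = truth$D,
                 replicates = reps, summary = summary),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Monte Carlo design evaluation:", x$scenario, "\n")
  print(x$summary)
  invisible(x)
}

#' Tidy Monte Carlo replicates
#' @param x An `mc_result`.
#' @param ... Unused.
#' @return The per-replicate tibble.
#' @export
tidy.mc_result <- function(x, ...) x$replicates

#' One-row Monte Carlo summary
#' @param x An `mc_result`.
#' @param ... Unused.
#' @return The summary tibble (mean RB, RMSE, exclusion count).
#' @export
glance.mc_result <- function(x, ...) x$summary

#' Total trapping effort in trap-nights
#'
#' @param traps A `trap_array` or a trap count.
#' @param n_occasions Occasions per session.
#' @param n_sessions Number of sessions.
#' @return `traps x occasions x sessions`.
#' @examples
#' trap_nights(build_grid(10, 10, 9.43), 4, 18) # 7200
#' @export
trap_nights <- function(traps, n_occasions, n_sessions = 1L) {
  k <- if (inherits(traps, "data.frame")) nrow(traps) else traps
  stopifnot(k >= 1, n_occasions >= 1, n_sessions >= 1)
  as.integer(k) * as.integer(n_occasions) * as.integer(n_sessions)
}

#' Capture efficiency
#'
#' Unique individuals caught per 100 trap-nights — the quick index field
#' programs use to track populations between full analyses.  Defined here
#' as `100 * distinct individuals / trap_nights`.
#'
#' @param ch A [capture_history()].
#' @param trap_nights Total trap-nights of effort, positive.
#' @return Captures per 100 trap-nights.
#' @export
capture_efficiency <- function(ch, trap_nights) {
  stopifnot(trap_nights > 0)
  100 * n_individuals(ch) / trap_nights
}

#' Plot replicate density estimates from Monte Carlo runs
#'
#' @param results A list of `mc_result` objects.
#' @return A ggplot object: boxplots of replicate relative bias by
#'   scenario.
#' @export
plot_mc_bias <- function(results) {
  df <- purrr::map_dfr(results, function(r) {
    dplyr::mutate(r$replicates[r$replicates$converged, ],
                  scenario = r$scenario)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$scenario, .data$rb)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "relative bias of density") +
    ggplot2::theme_minimal()
}
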