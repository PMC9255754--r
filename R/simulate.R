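#' Simulate a spatial population of activity centres
#'
#' Draws a Poisson number of animals with mean `D` times the region area
#' and places their activity centres uniformly over the rectangular region
#' covered by the habitat mask (the buffered rectangle, not the bare grid:
#' animals living off-grid must be available for capture, which is the
#' buffer's purpose).  Each animal receives a class label, `"F"` with
#' probability `pmix`.
#'
#' @param D True density, individuals per hectare (non-negative).
#' @param region A `habitat_mask`; its covered rectangle defines the
#'   simulation region and area.
#' @param pmix Proportion of class `"F"`, in `[0, 1]`.
#' @param seed Optional integer seed; when given the draw is reproducible.
#' @return A tibble of class `population` with columns `x`, `y`, `sex` and
#'   attributes `true_D`, `pmix`, `area_ha`.
#' @examples
#' mask <- build_mask(build_grid(10, 10, 9.43), 50, 5)
#' pop <- simulate_population(30, mask, seed = 1)
#' @export
simulate_population <- function(D, region, pmix = 0.5, seed = NULL) {
  stopifnot(is.numeric(D), length(D) == 1L, D >= 0,
            is.numeric(pmix), pmix >= 0, pmix <= 1)
  if (!is.null(seed)) set.seed(seed)
  sp <- attr(region, "spacing")
  xr <- range(region$x) + c(-sp / 2, sp / 2)
  yr <- range(region$y) + c(-sp / 2, sp / 2)
  area_ha <- diff(xr) * diff(yr) / 1e4
  N <- stats::rpois(1L, D * area_ha)
  pop <- tibble::tibble(
    x = stats::runif(N, xr[1], xr[2]),
    y = stats::runif(N, yr[1], yr[2]),
    sex = ifelse(stats::rbinom(N, 1L, pmix) == 1L, "F", "M")
  )
  structure(pop, true_D = D, pmix = pmix, area_ha = area_ha,
            class = c("population", class(tibble::tibble())))
}

#' Simulate a capture history from a population
#'
#' Runs the competing-risk capture process occasion by occasion.  Each
#' animal's per-trap capture probabilities follow [multicatch_probs()] for
#' its class parameters; under `exclusivity = "single_catch"` animals are
#' processed in a fresh uniformly random order each occasion and traps
#' already occupied are unavailable.  An optional behavioural response
#' rescales an individual's parameters after its first capture.  Animals
#' never captured do not appear in the output.
#'
#' @param pop A `population` from [simulate_population()].
#' @param traps A `trap_array`.
#' @param n_occasions Number of occasions.
#' @param params Either a single [detection_params()] applied to all
#'   animals or a named list `list(F = ..., M = ...)` of per-class
#'   parameters.
#' @param behavior_effect Optional `list(g0_mult = , sigma_mult = )`
#'   multiplying an individual's parameters after first capture
#'   (`> 1` on `g0_mult` = trap happy, `< 1` = trap shy).
#' @param exclusivity `"multi_catch"` (default) or `"single_catch"`.
#' @param seed Optional integer seed.
#' @param session Session label carried into the capture history.
#' @return A [capture_history()].
#' @export
simulate_capthist <- function(pop, traps, n_occasions, params,
                              behavior_effect = NULL,
                              exclusivity = c("multi_catch", "single_catch"),
                              seed = NULL, session = "sim") {
  exclusivity <- match.arg(exclusivity)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(params, "detection_params")) {
    params <- list(F = params, M = params)
  }
  stopifnot(all(c("F", "M") %in% names(params)) ||
              all(unique(pop$sex) %in% names(params)))
  N <- nrow(pop)
  K <- nrow(traps)
  if (N == 0 || K == 0) {
    return(capture_history(tibble::tibble(individual = character(),
                                          occasion = integer(),
                                          trap_id = character(),
                                          sex = character()),
                           n_occasions, session = session, traps = traps))
  }
  d <- sqrt(outer(pop$x, traps$x, "-")^2 + outer(pop$y, traps$y, "-")^2)
  ids <- sprintf("ind%03d", seq_len(N))
  caught_before <- rep(FALSE, N)

  hazard_row <- function(i) {
    p0 <- params[[pop$sex[i]]]
    if (caught_before[i] && !is.null(behavior_effect)) {
      g0 <- p0$g0 * (behavior_effect$g0_mult %||% 1)
      sg <- p0$sigma * (behavior_effect$sigma_mult %||% 1)
      g0 <- min(max(g0, 1e-8), 1 - 1e-8)
      p0 <- detection_params(g0, sg, p0$kind,
                             z = if (p0$kind == "HR") p0$z else NULL)
    }
    g <- detect_g(d[i, ], p0)
    -log1p(-pmin(g, 1 - 1e-12))
  }

  recs <- vector("list", n_occasions)
  for (s in seq_len(n_occasions)) {
    order_i <- if (exclusivity == "single_catch") sample.int(N) else seq_len(N)
    occupied <- rep(FALSE, K)
    out <- integer(0); who <- integer(0)
    for (i in order_i) {
      h <- hazard_row(i)
      if (exclusivity == "single_catch") h[occupied] <- 0
      H <- sum(h)
      if (H <= 0) next
      p_caught <- -expm1(-H)
      if (stats::runif(1L) < p_caught) {
        k <- sample.int(K, 1L, prob = h)
        out <- c(out, k); who <- c(who, i)
        occupied[k] <- TRUE
      }
    }
    caught_before[who] <- TRUE
    recs[[s]] <- tibble::tibble(individual = ids[who], occasion = s,
                                trap_id = traps$trap_id[out],
                                sex = pop$sex[who])
  }
  capture_history(dplyr::bind_rows(recs), n_occasions, session = session,
                  traps = traps)
}

#' Default multi-year study scenario
#'
#' Truth table for an 18-session emulation of a long-term coastal-marsh
#' small-mammal monitoring program: annual densities following the
#' published 2000-2017 estimates (roughly 9 to 54 individuals per
#' hectare), negative-exponential detection with sex-specific parameters,
#' equal sex ratio, a 10 x 10 grid at 9.43 m spacing and 4 occasions per
#' session.  The detection defaults (`g0` 0.32/0.16 and `sigma` 7/9 m for
#' females/males) were calibrated once against the program's published
#' numbers: they reproduce its per-session capture counts (about 38% of
#' the animals in the buffered region, roughly 716 individuals over 18
#' sessions), its density-estimate precision, and a between-capture
#' movement scale near the 11.9 m reported for the species, while keeping
#' the published qualitative sex pattern (males range wider, females are
#' more catchable at the centre).
#'
#' @param seed Base seed recorded in the scenario; per-session seeds are
#'   derived from it.
#' @return A list of class `study_scenario`: `truth` (a tibble with one row
#'   per session), `traps`, `n_occasions`, `seed`.
#' @export
default_study_scenario <- function(seed = 1L) {
  dens <- crescent_densities()
  truth <- tibble::tibble(
    session = as.character(dens$year),
    D = dens$full,
    g0_F = 0.32, g0_M = 0.16,
    sigma_F = 7, sigma_M = 9,
    pmix = 0.5
  )
  structure(list(truth = truth, traps = build_grid(10, 10, 9.43),
                 n_occasions = 4L, detectfn = "EX", buffer = 50,
                 seed = as.integer(seed)),
            class = "study_scenario")
}

#' Build a custom study scenario
#'
#' @param truth A tibble with columns `session`, `D`, `g0_F`, `g0_M`,
#'   `sigma_F`, `sigma_M`, `pmix`.
#' @param traps A `trap_array`.
#' @param n_occasions Occasions per session.
#' @param detectfn Detection function kind for the generator.
#' @param buffer Mask/region buffer in metres.
#' @param seed Base seed.
#' @return A `study_scenario` list.
#' @export
study_scenario <- function(truth, traps, n_occasions = 4L, detectfn = "EX",
                           buffer = 50, seed = 1L) {
  need <- c("session", "D", "g0_F", "g0_M", "sigma_F", "sigma_M", "pmix")
  truth <- tibble::as_tibble(truth)
  if (!all(need %in% names(truth)) || nrow(truth) < 1) {
    stop("truth table needs columns ", paste(need, collapse = ", "),
         " and at least one session", call. = FALSE)
  }
  structure(list(truth = truth, traps = traps,
                 n_occasions = as.integer(n_occasions),
                 detectfn = detectfn, buffer = buffer,
                 seed = as.integer(seed)),
            class = "study_scenario")
}

scenario_params <- function(row, detectfn) {
  list(F = detection_params(row$g0_F, row$sigma_F, detectfn),
       M = detection_params(row$g0_M, row$sigma_M, detectfn))
}

#' Simulate a full multi-session study
#'
#' Generates one capture history per session of a [study_scenario()],
#' with a truth ledger recording the generating parameters and per-session
#' seeds.  Per-session seeds are derived deterministically from the base
#' seed, so the whole study is reproducible end to end.
#'
#' @param scenario A `study_scenario`.
#' @param mask_spacing Mask cell side (metres) for the simulation region;
#'   defaults to `buffer / 10`.
#' @return A list of class `synth_study`: `sessions` (named list of
#'   [capture_history()]), `truth` (ledger tibble, including the realised
#'   number of individuals captured), `traps`, `mask`.
#' @examples
#' \donttest{
#' study <- synth_study(default_study_scenario(seed = 42))
#' study$truth
#' }
#' @export
synth_study <- function(scenario, mask_spacing = NULL) {
  stopifnot(inherits(scenario, "study_scenario"))
  mask <- build_mask(scenario$traps, scenario$buffer, mask_spacing)
  truth <- scenario$truth
  seeds <- (scenario$seed + 1009L * seq_len(nrow(truth))) %% .Machine$integer.max
  sessions <- purrr::map(seq_len(nrow(truth)), function(j) {
    row <- truth[j, ]
    pop <- simulate_population(row$D, mask, pmix = row$pmix, seed = seeds[j])
    simulate_capthist(pop, scenario$traps, scenario$n_occasions,
                      params = scenario_params(row, scenario$detectfn),
                      session = row$session)
  })
  names(sessions) <- truth$session
  ledger <- dplyr::mutate(truth,
                          seed = seeds,
                          n_captured = unname(purrr::map_int(sessions, n_individuals)),
                          n_records = unname(purrr::map_int(sessions, nrow)))
  structure(list(sessions = sessions, truth = ledger,
                 traps = scenario$traps, mask = mask,
                 n_occasions = scenario$n_occasions,
                 detectfn = scenario$detectfn),
            class = "synth_study")
}
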