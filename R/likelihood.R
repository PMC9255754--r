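#' Specify a SECR detection model
#'
#' Defines the detection function and which covariates act on its
#' parameters.  `g0` (baseline capture probability) and `sigma` (spatial
#' scale) may each carry a `"time"` effect (a separate level per occasion),
#' a `"behavior"` effect (a permanent shift after an individual's first
#' capture — "trap happy"/"trap shy"), or a `"sex"` effect (a two-class
#' finite mixture with the class observed for sexed individuals and the
#' class proportion `pmix` estimated).  Time and behaviour are mutually
#' exclusive on the same parameter.
#'
#' @param detectfn `"EX"` (negative exponential), `"HN"` (half-normal) or
#'   `"HR"` (hazard rate).
#' @param g0_effects,sigma_effects Character subsets of
#'   `c("time", "behavior", "sex")`.
#' @param mixture Estimate the sex-class proportion?  Defaults to `TRUE`
#'   whenever either parameter has a sex effect.
#' @return A list of class `secr_model`.
#' @examples
#' secr_model("EX", g0_effects = "sex", sigma_effects = "sex")
#' @export
secr_model <- function(detectfn = c("EX", "HN", "HR"),
                       g0_effects = character(),
                       sigma_effects = character(),
                       mixture = NULL) {
  detectfn <- match.arg(detectfn)
  ok <- c("time", "behavior", "sex")
  if (!all(g0_effects %in% ok) || !all(sigma_effects %in% ok)) {
    stop("effects must be drawn from \"time\", \"behavior\", \"sex\"", call. = FALSE)
  }
  for (eff in list(g0_effects, sigma_effects)) {
    if (all(c("time", "behavior") %in% eff)) {
      stop("time and behaviour effects cannot act on the same parameter",
           call. = FALSE)
    }
  }
  has_sex <- "sex" %in% c(g0_effects, sigma_effects)
  if (is.null(mixture)) mixture <- has_sex
  if (has_sex && !mixture) {
    stop("a sex effect requires the mixture proportion to be estimated",
         call. = FALSE)
  }
  # mixture without sex effects is allowed: detection is shared across
  # classes but the class proportion is still estimated from the labels,
  # keeping the likelihood comparable (AIC) with sex-effect models
  structure(list(detectfn = detectfn,
                 g0_effects = sort(unique(g0_effects)),
                 sigma_effects = sort(unique(sigma_effects)),
                 mixture = mixture),
            class = "secr_model")
}

n_beta <- function(effects, S) {
  1L + ("time" %in% effects) * (S - 1L) + ("behavior" %in% effects) +
    ("sex" %in% effects)
}

# additive link-scale expansion to the [class, occasion, state] array
expand_betas <- function(beta, effects, S, nclass) {
  arr <- array(beta[1], dim = c(nclass, S, 2L))
  i <- 1L
  if ("time" %in% effects && S > 1) {
    for (s in 2:S) {
      i <- i + 1L
      arr[, s, ] <- arr[, s, ] + beta[i]
    }
  }
  if ("behavior" %in% effects) {
    i <- i + 1L
    arr[, , 2L] <- arr[, , 2L] + beta[i]
  }
  if ("sex" %in% effects && nclass == 2L) {
    i <- i + 1L
    arr[2L, , ] <- arr[2L, , ] + beta[i]
  }
  arr
}

theta_layout <- function(spec, S) {
  kg <- n_beta(spec$g0_effects, S)
  ks <- n_beta(spec$sigma_effects, S)
  nms <- c("logD",
           paste0("g0.", beta_names(spec$g0_effects, S)),
           paste0("sigma.", beta_names(spec$sigma_effects, S)),
           if (spec$detectfn == "HR") "log(z-1)",
           if (spec$mixture) "logit(pmix)")
  list(k = length(nms), kg = kg, ks = ks, names = nms,
       i_g0 = 1L + seq_len(kg),
       i_sg = 1L + kg + seq_len(ks),
       i_z = if (spec$detectfn == "HR") 1L + kg + ks + 1L else integer(0),
       i_pi = if (spec$mixture) 1L + kg + ks +
         (spec$detectfn == "HR") + 1L else integer(0))
}

beta_names <- function(effects, S) {
  c("(Intercept)",
    if ("time" %in% effects && S > 1) paste0("t", 2:S),
    if ("behavior" %in% effects) "b",
    if ("sex" %in% effects) "sexM")
}

# distances, capture matrices, and everything theta-independent
secr_context <- function(ch, traps, mask, spec) {
  mats <- capthist_matrices(ch, traps)
  nclass <- if (spec$mixture) 2L else 1L
  sexcl <- mats$sex
  if (nclass == 1L) sexcl <- rep(1L, length(sexcl))
  if (nclass == 2L && any(sexcl == 0L) && all(sexcl == 0L)) {
    # all-unknown data still marginalise correctly; nothing to do
  }
  dist <- sqrt(outer(mask$x, traps$x, "-")^2 + outer(mask$y, traps$y, "-")^2)
  list(dist = dist, cell_ha = attr(mask, "cell_area_ha"),
       S = mats$S, caps = mats$caps, sexcl = as.integer(sexcl),
       detectfn = match(spec$detectfn, c("HN", "EX", "HR")) - 1L,
       nclass = nclass, layout = theta_layout(spec, mats$S), spec = spec)
}

nll_from_context <- function(ctx, theta) {
  lay <- ctx$layout
  if (length(theta) != lay$k) {
    stop(sprintf("theta must have length %d for this model", lay$k), call. = FALSE)
  }
  if (any(!is.finite(theta))) stop("theta must be finite", call. = FALSE)
  spec <- ctx$spec
  S <- ctx$S
  nclass <- ctx$nclass
  g0_arr <- stats::plogis(expand_betas(theta[lay$i_g0], spec$g0_effects, S, nclass))
  sg_arr <- exp(expand_betas(theta[lay$i_sg], spec$sigma_effects, S, nclass))
  z_arr <- array(if (spec$detectfn == "HR") 1 + exp(theta[lay$i_z]) else 0,
                 dim = c(nclass, S, 2L))
  pmix <- if (spec$mixture) stats::plogis(theta[lay$i_pi]) else 1
  pi_u <- if (nclass == 2L) c(pmix, 1 - pmix) else 1
  any_behavior <- "behavior" %in% c(spec$g0_effects, spec$sigma_effects)
  secr_nll_cpp(ctx$dist, ctx$cell_ha, S, ctx$caps, ctx$sexcl, ctx$detectfn,
               as.numeric(g0_arr), as.numeric(sg_arr), as.numeric(z_arr),
               exp(theta[1]), pi_u, any_behavior)
}

#' SECR negative log-likelihood
#'
#' Evaluates the full (Poisson-n) spatially explicit capture-recapture
#' negative log-likelihood for multi-catch traps at a transformed parameter
#' vector.  The latent activity centre of each animal is integrated over
#' the habitat mask; the expected number of detected animals
#' `Lambda = D a sum_m sum_u pi_u pdot(X_m; theta_u)` enters through the
#' Poisson term, and each observed history contributes
#' `log(D a sum_m pi * Pr(history | X_m))`.  The additive `log(n!)`
#' constant is omitted throughout, consistently for all models on the same
#' data.
#'
#' @param ch A [capture_history()].
#' @param traps A `trap_array`.
#' @param mask A `habitat_mask` from [build_mask()].
#' @param spec A [secr_model()].
#' @param theta Parameter vector on link scales, in the order `log D`, the
#'   `g0` coefficients (logit scale), the `sigma` coefficients (log scale),
#'   `log(z - 1)` for the hazard-rate form, and `logit(pmix)` for mixture
#'   models.
#' @return The negative log-likelihood (a scalar).
#' @export
negloglik <- function(ch, traps, mask, spec, theta) {
  nll_from_context(secr_context(ch, traps, mask, spec), theta)
}

default_starts <- function(ch, traps, mask, spec) {
  lay <- theta_layout(spec, n_occasions(ch))
  n <- n_individuals(ch)
  area <- mask_area(mask)
  D0 <- max(n, 1) / area
  # sigma: half the mean displacement between successive captures of the
  # same individual at different traps; falls back to half the trap spacing
  disp <- numeric(0)
  if (nrow(ch) > 0) {
    xy <- traps[match(ch$trap_id, traps$trap_id), c("x", "y")]
    byind <- split(seq_len(nrow(ch)), ch$individual)
    disp <- unlist(lapply(byind, function(ii) {
      if (length(ii) < 2) return(numeric(0))
      sqrt(diff(xy$x[ii])^2 + diff(xy$y[ii])^2)
    }))
    disp <- disp[disp > 0]
  }
  sigma0 <- if (length(disp) > 0) mean(disp) / 2 else
    mean_nearest_trap_distance(traps) / 2
  g0_0 <- if (n > 0) nrow(ch) / (n * n_occasions(ch)) else 0.2
  g0_0 <- min(max(g0_0, 0.05), 0.8)
  pmix0 <- 0.5
  if (spec$mixture && nrow(ch) > 0) {
    first <- ch[!duplicated(ch$individual), , drop = FALSE]
    pf <- mean(first$sex == "F")
    if (is.finite(pf)) pmix0 <- min(max(pf, 0.1), 0.9)
  }
  theta <- c(log(D0),
             stats::qlogis(g0_0), rep(0, lay$kg - 1L),
             log(sigma0), rep(0, lay$ks - 1L),
             if (spec$detectfn == "HR") log(1.5),
             if (spec$mixture) stats::qlogis(pmix0))
  stats::setNames(theta, lay$names)
}

#' Fit a SECR model by maximum likelihood
#'
#' Maximises the full SECR likelihood over link-scale parameters with
#' [stats::nlm()], then obtains standard errors from the inverse of the
#' numerically differentiated Hessian with the delta method applied on the
#' back-transformed scales.
#'
#' Fits on sparse data are flagged rather than refused: fewer than 15
#' individuals or fewer than 5 spatial recaptures sets the `"unstable"`
#' flag, and a singular Hessian or wildly imprecise density
#' (`CV(D) > 1`) sets `"non_identifiable"`.
#'
#' @inheritParams negloglik
#' @param starts Optional named start vector on link scales; defaults to
#'   data-driven values (density from `n` over the mask area, `sigma` from
#'   half the mean between-recapture displacement, `g0` from the naive
#'   per-occasion capture frequency).
#' @param iterlim Maximum optimiser iterations.
#' @param hessian Compute the Hessian-based variance matrix?  Set `FALSE`
#'   when only the maximised likelihood is needed (e.g. AIC screening);
#'   standard errors are then `NA`.
#' @return An object of class `secr_fit`: estimates with SEs, the
#'   log-likelihood, parameter count, AIC, convergence flag and
#'   diagnostics.  Use [tidy()][generics::tidy] and
#'   [glance()][generics::glance] to extract tabular summaries.
#' @examples
#' \donttest{
#' traps <- build_grid(6, 6, 9.43)
#' mask <- build_mask(traps, 50, 10)
#' pop <- simulate_population(25, mask, seed = 1)
#' ch <- simulate_capthist(pop, traps, 4,
#'   params = detection_params(0.3, 12, "EX"), seed = 2)
#' fit <- fit_secr(ch, traps, mask, secr_model("EX"))
#' glance(fit)
#' }
#' @export
fit_secr <- function(ch, traps, mask, spec = secr_model("EX"), starts = NULL,
                     iterlim = 300L, hessian = TRUE) {
  ctx <- secr_context(ch, traps, mask, spec)
  lay <- ctx$layout
  if (is.null(starts)) starts <- default_starts(ch, traps, mask, spec)
  if (length(starts) != lay$k) {
    stop(sprintf("`starts` must have length %d", lay$k), call. = FALSE)
  }
  flags <- character(0)
  n <- n_individuals(ch)
  n_sp <- n_spatial_recaptures(ch)
  if (n < 15 || n_sp < 5) flags <- c(flags, "unstable")
  if (n < 2 && n_sp == 0) flags <- c(flags, "too_sparse")

  f <- function(theta) {
    v <- tryCatch(nll_from_context(ctx, theta), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- suppressWarnings(stats::nlm(f, starts, iterlim = iterlim,
                                     gradtol = 1e-7, steptol = 1e-9))
  theta_hat <- stats::setNames(opt$estimate, lay$names)
  nll_min <- opt$minimum
  converged <- opt$code %in% c(1, 2) && is.finite(nll_min) && nll_min < 1e9
  grad_norm <- sqrt(sum(opt$gradient^2))

  vcov <- NULL
  if (hessian) {
    hess <- tryCatch(stats::optimHess(theta_hat, f), error = function(e) NULL)
    if (!is.null(hess)) {
      vcov <- tryCatch(solve(hess), error = function(e) NULL)
      if (!is.null(vcov) && any(diag(vcov) < 0)) vcov <- NULL
    }
    if (is.null(vcov)) flags <- c(flags, "non_identifiable")
  }
  if (is.null(vcov)) vcov <- matrix(NA_real_, lay$k, lay$k)
  se_theta <- sqrt(diag(vcov))

  D_hat <- exp(theta_hat[1])
  SE_D <- D_hat * se_theta[1]
  if (is.finite(SE_D) && is.finite(D_hat) && SE_D / D_hat > 1) {
    flags <- unique(c(flags, "non_identifiable"))
  }
  pmix_hat <- if (spec$mixture) stats::plogis(theta_hat[lay$i_pi]) else NA_real_
  SE_pmix <- if (spec$mixture) {
    pmix_hat * (1 - pmix_hat) * se_theta[lay$i_pi]
  } else NA_real_

  coefs <- tibble::tibble(
    term = lay$names,
    estimate = unname(theta_hat),
    std.error = unname(se_theta)
  )

  fit <- structure(list(
    D_hat = unname(D_hat), SE_D = unname(SE_D),
    pmix_hat = unname(pmix_hat), SE_pmix = unname(SE_pmix),
    coefficients = coefs, vcov = vcov,
    log_likelihood = -nll_min, n_parameters = lay$k,
    AIC = 2 * nll_min + 2 * lay$k,
    convergence = converged, flags = flags, grad_norm = grad_norm,
    nlm_code = opt$code, n = n, n_records = nrow(ch),
    n_spatial_recaptures = n_sp,
    spec = spec, S = ctx$S, mask_area_ha = mask_area(mask),
    session = attr(ch, "session"),
    theta = theta_hat
  ), class = "secr_fit")
  fit$detection <- detection_estimates(fit)
  fit
}

#' Natural-scale detection parameter estimates
#'
#' Back-transforms the fitted link-scale coefficients to per-class,
#' per-occasion, per-behaviour-state values of `g0` and `sigma`, with
#' delta-method standard errors.
#'
#' @param fit A `secr_fit`.
#' @return A tibble with columns `class`, `occasion`, `state`, `g0`,
#'   `se_g0`, `sigma`, `se_sigma`.
#' @export
detection_estimates <- function(fit) {
  spec <- fit$spec
  S <- fit$S
  lay <- theta_layout(spec, S)
  nclass <- if (spec$mixture) 2L else 1L
  classes <- if (nclass == 2L) c("F", "M") else "all"
  states <- c("naive", "caught")
  any_b <- "behavior" %in% c(spec$g0_effects, spec$sigma_effects)
  grid <- tidyr::expand_grid(class = classes, occasion = seq_len(S),
                             state = if (any_b) states else states[1])

  one_par <- function(effects, idx, invlink, dinvlink, u, s, b) {
    x <- numeric(length(idx)); x[1] <- 1; i <- 1L
    if ("time" %in% effects && S > 1 && s >= 2) x[i + s - 1L] <- 1
    if ("time" %in% effects) i <- i + S - 1L
    if ("behavior" %in% effects) {
      i <- i + 1L
      if (b == 2L) x[i] <- 1
    }
    if ("sex" %in% effects && u == 2L) x[i + 1L] <- 1
    eta <- sum(x * fit$theta[idx])
    v <- if (all(is.finite(fit$vcov[idx, idx]))) {
      drop(t(x) %*% fit$vcov[idx, idx, drop = FALSE] %*% x)
    } else NA_real_
    c(invlink(eta), dinvlink(eta) * sqrt(v))
  }

  res <- purrr::pmap_dfr(grid, function(class, occasion, state) {
    u <- match(class, c("F", "M"), nomatch = 1L)
    b <- match(state, states)
    g <- one_par(spec$g0_effects, lay$i_g0, stats::plogis,
                 function(e) stats::plogis(e) * (1 - stats::plogis(e)),
                 u, occasion, b)
    sg <- one_par(spec$sigma_effects, lay$i_sg, exp, exp, u, occasion, b)
    tibble::tibble(class = class, occasion = occasion, state = state,
                   g0 = g[1], se_g0 = g[2], sigma = sg[1], se_sigma = sg[2])
  })
  res
}

#' @export
print.secr_fit <- function(x, ...) {
  cat("SECR fit (", x$spec$detectfn, " detection)\n", sep = "")
  cat(sprintf("  n = %d individuals, %d records, %d spatial recaptures, S = %d\n",
              x$n, x$n_records, x$n_spatial_recaptures, x$S))
  cat(sprintf("  D = %.2f / ha (SE %.2f)\n", x$D_hat, x$SE_D))
  if (!is.na(x$pmix_hat)) {
    cat(sprintf("  pmix(F) = %.3f (SE %.3f)\n", x$pmix_hat, x$SE_pmix))
  }
  cat(sprintf("  logLik = %.3f, k = %d, AIC = %.3f\n",
              x$log_likelihood, x$n_parameters, x$AIC))
  cat(sprintf("  converged: %s%s\n", x$convergence,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Tidy a SECR fit
#' @param x A `secr_fit`.
#' @param ... Unused.
#' @return A tibble of link-scale coefficients with standard errors.
#' @export
tidy.secr_fit <- function(x, ...) x$coefficients

#' One-row summary of a SECR fit
#' @param x A `secr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: density estimate and SE, mixture proportion,
#'   log-likelihood, parameter count, AIC, convergence, sample sizes.
#' @export
glance.secr_fit <- function(x, ...) {
  tibble::tibble(
    D_hat = x$D_hat, SE_D = x$SE_D, pmix = x$pmix_hat,
    logLik = x$log_likelihood, k = x$n_parameters, AIC = x$AIC,
    converged = x$convergence,
    flags = paste(x$flags, collapse = ";"),
    n = x$n, n_records = x$n_records,
    n_spatial_recaptures = x$n_spatial_recaptures
  )
}

#' @export
logLik.secr_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_parameters,
            nobs = object$n, class = "logLik")
}

#' Plot fitted detection curves
#'
#' Detection probability against distance from the activity centre, one
#' curve per class (occasion 1, pre-capture state).
#'
#' @param object A `secr_fit`.
#' @param max_d Largest distance to draw, metres.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.secr_fit <- function(object, max_d = NULL, ...) {
  det <- object$detection
  det <- det[det$occasion == 1 & det$state == det$state[1], , drop = FALSE]
  if (is.null(max_d)) max_d <- 4 * max(det$sigma)
  z_hat <- if (object$spec$detectfn == "HR") {
    1 + exp(object$theta[theta_layout(object$spec, object$S)$i_z])
  } else NULL
  curves <- purrr::pmap_dfr(det, function(class, g0, sigma, ...) {
    d <- seq(0, max_d, length.out = 200)
    p <- detection_params(g0, sigma, object$spec$detectfn, z = z_hat)
    tibble::tibble(class = class, d = d, g = detect_g(d, p))
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$d, .data$g, colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from activity centre (m)",
                  y = "per-occasion capture probability",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Rank SECR fits by AIC
#'
#' @param fits A list of `secr_fit` objects fitted to the same data.
#' @param labels Optional model labels; defaults to a compact description.
#' @return A tibble sorted by AIC with `dAIC` and Akaike weights
#'   (weights sum to 1).
#' @export
aic_rank <- function(fits, labels = NULL) {
  stopifnot(length(fits) >= 1, all(purrr::map_lgl(fits, inherits, "secr_fit")))
  ns <- purrr::map_int(fits, "n")
  recs <- purrr::map_int(fits, "n_records")
  if (length(unique(ns)) > 1 || length(unique(recs)) > 1) {
    stop("AIC comparison requires fits to the same data", call. = FALSE)
  }
  mixes <- purrr::map_lgl(fits, ~ .x$spec$mixture)
  if (length(unique(mixes)) > 1) {
    stop("mixture and non-mixture fits model different data (the sex labels) ",
         "and cannot be AIC-ranked together", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- purrr::map_chr(fits, function(f) {
      eff <- function(e) if (length(e)) paste(e, collapse = "+") else "1"
      sprintf("%s g0~%s sigma~%s", f$spec$detectfn,
              eff(f$spec$g0_effects), eff(f$spec$sigma_effects))
    })
  }
  out <- tibble::tibble(
    model = labels,
    k = purrr::map_int(fits, "n_parameters"),
    logLik = purrr::map_dbl(fits, "log_likelihood"),
    AIC = purrr::map_dbl(fits, "AIC")
  )
  out <- dplyr::arrange(out, .data$AIC)
  out$dAIC <- out$AIC - out$AIC[1]
  w <- exp(-out$dAIC / 2)
  out$weight <- w / sum(w)
  out
}

#' Summarise densities over periods of years
#'
#' Computes the arithmetic mean (with min/max and their years) of annual
#' density estimates within one or more year ranges.
#'
#' @param data A data frame with a year column and a density column, or a
#'   list of `secr_fit` objects whose `session` labels are years.
#' @param periods A list of length-2 numeric ranges `c(from, to)`
#'   (inclusive); `NULL` means one period spanning all years.
#' @param year_col,density_col Column names used when `data` is a data
#'   frame.
#' @return A tibble with one row per period: `period`, `n_years`,
#'   `mean_D`, `min_D`, `year_min`, `max_D`, `year_max`.
#' @examples
#' d <- crescent_densities()
#' summarize_densities(d, list(c(2000, 2017), c(2000, 2010), c(2011, 2017)),
#'                     density_col = "full")
#' @export
summarize_densities <- function(data, periods = NULL, year_col = "year",
                                density_col = "density") {
  if (is.list(data) && !is.data.frame(data) &&
      all(purrr::map_lgl(data, inherits, "secr_fit"))) {
    data <- tibble::tibble(
      year = as.numeric(purrr::map_chr(data, ~ as.character(.x$session))),
      density = purrr::map_dbl(data, "D_hat")
    )
    year_col <- "year"; density_col <- "density"
  }
  data <- tibble::as_tibble(data)
  yr <- data[[year_col]]; D <- data[[density_col]]
  if (is.null(yr) || is.null(D)) {
    stop("`data` must contain the year and density columns", call. = FALSE)
  }
  if (is.null(periods)) periods <- list(range(yr))
  purrr::map_dfr(periods, function(p) {
    stopifnot(length(p) == 2)
    sel <- yr >= p[1] & yr <= p[2]
    if (!any(sel)) stop("a period selects no years", call. = FALSE)
    ys <- yr[sel]; Ds <- D[sel]
    tibble::tibble(
      period = paste0(p[1], "-", p[2]),
      n_years = sum(sel),
      mean_D = mean(Ds),
      min_D = min(Ds), year_min = ys[which.min(Ds)],
      max_D = max(Ds), year_max = ys[which.max(Ds)]
    )
  })
}
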