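# Small builders and independent oracles shared across test files.

tiny_traps <- function(xy) {
  gridsecr:::new_trap_array(tibble::tibble(
    trap_id = sprintf("A%02d", seq_len(nrow(xy))), x = xy[, 1], y = xy[, 2]
  ))
}

tiny_mask <- function(xy, cell_ha = 0.01, spacing = 10) {
  structure(tibble::tibble(x = xy[, 1], y = xy[, 2]),
            cell_area_ha = cell_ha, spacing = spacing, buffer = 0,
            area_ha = nrow(xy) * cell_ha,
            class = c("habitat_mask", class(tibble::tibble())))
}

study_params <- function() {
  list(F = detection_params(0.32, 7, "EX"),
       M = detection_params(0.16, 9, "EX"))
}

study_spec <- function() {
  secr_model("EX", g0_effects = "sex", sigma_effects = "sex")
}

# Brute-force SECR negative log-likelihood by exhaustive enumeration of
# per-occasion outcomes at every mask point, built on the pure-R detection
# layer only (independent of the compiled kernel).  Classes: a named list of
# detection_params; pi_u a matching named vector of class proportions.
# caps: n x S matrix of trap indices (0 = not caught); class_of: names into
# `classes` per individual, NA = unknown (marginalised).
brute_nll <- function(traps, mask, caps, class_of, classes, pi_u, D) {
  a <- attr(mask, "cell_area_ha")
  M <- nrow(mask)
  S <- if (is.matrix(caps)) ncol(caps) else 0L
  outcome_probs <- function(m, cls) {
    multicatch_probs(c(mask$x[m], mask$y[m]), traps, classes[[cls]])$prob
  }
  pdot_m <- function(m, cls) {
    pr <- outcome_probs(m, cls)
    none <- pr[length(pr)]
    1 - none^S
  }
  Lambda <- D * a * sum(vapply(seq_len(M), function(m) {
    sum(vapply(names(classes), function(u) pi_u[[u]] * pdot_m(m, u), 0))
  }, 0))
  nll <- Lambda
  n <- if (is.matrix(caps)) nrow(caps) else 0L
  K <- nrow(traps)
  for (i in seq_len(n)) {
    us <- if (is.na(class_of[i])) names(classes) else class_of[i]
    li <- 0
    for (u in us) {
      for (m in seq_len(M)) {
        pr <- outcome_probs(m, u)
        contrib <- prod(vapply(seq_len(S), function(s) {
          k <- caps[i, s]
          if (k == 0) pr[K + 1] else pr[k]
        }, 0))
        li <- li + pi_u[[u]] * contrib
      }
    }
    nll <- nll - log(D * a * li)
  }
  nll
}

# random tiny SECR instance (<= 2 traps, <= 2 occasions, <= 4 mask points,
# <= 2 individuals) for enumeration-oracle comparisons
make_small_instance <- function(seed) {
  set.seed(seed)
  K <- sample(1:2, 1)
  traps <- tiny_traps(cbind(runif(K, 0, 14), runif(K, 0, 14)))
  M <- sample(2:4, 1)
  mask <- tiny_mask(cbind(runif(M, -10, 24), runif(M, -10, 24)))
  S <- sample(1:2, 1)
  n <- sample(0:2, 1)
  caps <- matrix(0L, n, S)
  sex <- character(n)
  for (i in seq_len(n)) {
    repeat {
      caps[i, ] <- sample(0:K, S, replace = TRUE)
      if (any(caps[i, ] > 0)) break
    }
    sex[i] <- sample(c("F", "M"), 1)
  }
  rec <- which(caps > 0, arr.ind = TRUE)
  records <- tibble::tibble(
    individual = paste0("i", rec[, 1]),
    occasion = as.integer(rec[, 2]),
    trap_id = traps$trap_id[caps[rec]],
    sex = sex[rec[, 1]]
  )
  ch <- capture_history(records, S, traps = traps)
  list(traps = traps, mask = mask, ch = ch, caps = caps, sex = sex, S = S)
}

# deterministic small capture history on a given trap array
toy_capthist <- function(traps, n_occasions = 2) {
  capture_history(tibble::tibble(
    individual = c("i1", "i1", "i2"),
    occasion = c(1L, 2L, 2L),
    trap_id = traps$trap_id[c(1, 2, 2)],
    sex = c("F", "F", "M")
  ), n_occasions, traps = traps)
}
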