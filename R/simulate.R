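# Reaction-network construction for the disproportionation simulator.
# Species are free glucans (Gn, pNPGn) and enzyme-held donor fragments
# ("E:Gn"). Reactions:
#   cleavage   Gn --(k_c * w(register))--> released + E:Gd     (linear)
#   transfer   E:Gd + A --(k_t * w_acc(A))--> G(d+|A|)         (bilinear)
#   hydrolysis E:Gd --(k_h)--> Gd                              (linear)
build_reaction_network <- function(initial_amounts, profile) {
  init_parsed <- purrr::map(names(initial_amounts), parse_species)
  has_pnp <- any(purrr::map_chr(init_parsed, "label") == "pNP")
  max_init <- max(purrr::map_int(init_parsed, "length"))
  if (max_init > profile$max_length) {
    stop_gt("Initial species exceed the profile's length cap.", "gt_validation_error")
  }

  glucans <- paste0("G", seq_len(profile$max_length))
  pnp <- if (has_pnp) paste0("pNPG", seq_len(profile$max_pnp_length)) else character(0)
  free_species <- c(glucans, pnp)
  inter <- paste0("E:G", seq_len(profile$max_length - 1L))
  all_names <- c(free_species, inter)
  idx <- stats::setNames(seq_along(all_names), all_names)

  r1 <- integer(0); r2 <- integer(0); k <- numeric(0)
  sto <- list()  # per reaction: named delta vector (indices)
  add_rx <- function(i1, i2, rate, delta) {
    r1 <<- c(r1, i1); r2 <<- c(r2, i2); k <<- c(k, rate)
    sto[[length(sto) + 1L]] <<- delta
  }

  truncating <- 0L
  for (sp in free_species) {
    p <- parse_species(sp)
    regs <- enumerate_registers(p$length, profile, p$label)
    regs <- regs[regs$productive & regs$weight > 0, , drop = FALSE]
    if (!nrow(regs)) next
    for (i in seq_len(nrow(regs))) {
      rel <- species_name(regs$released_length[i], regs$released_label[i])
      donor <- paste0("E:G", regs$donor_length[i])
      delta <- c(-1, 1, 1)
      names(delta) <- c(sp, rel, donor)
      add_rx(idx[[sp]], 0L, profile$cleavage_rate * regs$weight[i],
             tapply(delta, names(delta), sum))
    }
  }
  for (d in seq_len(profile$max_length - 1L)) {
    donor <- paste0("E:G", d)
    # hydrolysis
    if (profile$hydrolysis_rate > 0) {
      delta <- c(-1, 1); names(delta) <- c(donor, paste0("G", d))
      add_rx(idx[[donor]], 0L, profile$hydrolysis_rate,
             tapply(delta, names(delta), sum))
    }
    # transfer to each acceptor
    if (profile$transfer_rate > 0) {
      for (a in free_species) {
        pa <- parse_species(a)
        w <- acceptor_weight(pa$length, pa$label, profile)
        if (w <= 0) next
        cap <- if (pa$label == "pNP") profile$max_pnp_length else profile$max_length
        new_len <- d + pa$length
        if (new_len > cap) { truncating <- truncating + 1L; new_len <- cap }
        prod_sp <- species_name(new_len, pa$label)
        delta <- c(-1, -1, 1); names(delta) <- c(donor, a, prod_sp)
        add_rx(idx[[donor]], idx[[a]], profile$transfer_rate * w,
               tapply(delta, names(delta), sum))
      }
    }
  }

  m <- length(k)
  S <- matrix(0, nrow = length(all_names), ncol = m,
              dimnames = list(all_names, NULL))
  for (j in seq_len(m)) S[names(sto[[j]]), j] <- sto[[j]]
  units <- vapply(all_names, function(nm) {
    parse_species(sub("^E:", "", nm))$length
  }, integer(1))
  list(species = all_names, idx = idx, r1 = r1, r2 = r2, k = k, S = S,
       units = units, n_free = length(free_species), truncating = truncating)
}

#' Simulate maltooligosaccharide disproportionation
#'
#' Integrates the subsite-binding reaction model: substrates bind across the
#' subsite array in proportion to register weights, productive registers are
#' cleaved between -1 and +1, the acceptor-side fragment is released, and
#' the enzyme-held donor fragment is resolved by transfer to a bound glucan
#' acceptor or by hydrolysis. The deterministic engine integrates the
#' mass-action rate equations (deSolve); the stochastic engine is an exact
#' Gillespie direct-method simulation on molecule counts.
#'
#' @param initial Named numeric vector (or tibble `species`, `amount`) of
#'   starting amounts: mM for deterministic, molecule counts for stochastic.
#' @param profile A [subsite_profile()].
#' @param duration Simulated time, minutes (> 0).
#' @param times Output time grid (default 101 points over the duration).
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param seed Random seed for the stochastic engine; identical seeds give
#'   identical trajectories.
#' @param omega Molecules per mM: scales bilinear propensities so that a
#'   stochastic run with counts `omega * mM` matches the deterministic run
#'   (default 1).
#' @return An object of class `gt_sim`: tidy trajectory tibble (`time`,
#'   `species`, `amount`, `kind`), plus the network and run metadata.
#'   Supports [tidy()], [glance()] and `autoplot()`.
#' @export
simulate_disproportionation <- function(initial, profile, duration,
                                        times = NULL,
                                        mode = c("deterministic", "stochastic"),
                                        seed = NULL, omega = 1) {
  mode <- match.arg(mode)
  assert_scalar_num(duration, "duration", positive = TRUE)
  if (is.data.frame(initial)) initial <- stats::setNames(initial$amount, initial$species)
  state0 <- reaction_state(initial)  # validates names/nonnegativity
  times <- times %||% seq(0, duration, length.out = 101L)
  if (min(times) > 0) times <- c(0, times)
  times <- sort(unique(times[times <= duration + 1e-12]))

  net <- build_reaction_network(state0$amounts, profile)
  y0 <- stats::setNames(numeric(length(net$species)), net$species)
  y0[names(state0$amounts)] <- state0$amounts

  traj <- if (mode == "deterministic") {
    integrate_deterministic(y0, net, times)
  } else {
    run_gillespie(y0, net, times, seed = seed, omega = omega)
  }

  total0 <- sum(net$units * y0)
  total_end <- sum(net$units * traj[nrow(traj), -1])
  leak <- total0 - total_end
  if (net$truncating > 0 && abs(leak) > 1e-9 * max(total0, 1)) {
    warning(sprintf("Length-cap truncation leaked %.3g glucose units over the run.",
                    leak), call. = FALSE)
  }

  tidy_traj <- tibble::as_tibble(as.data.frame(traj)) |>
    rlang::set_names(c("time", net$species)) |>
    tidyr::pivot_longer(-"time", names_to = "species", values_to = "amount") |>
    dplyr::mutate(kind = ifelse(startsWith(.data$species, "E:"),
                                "intermediate", "free"))

  structure(list(trajectory = tidy_traj, species = net$species,
                 units = net$units, mode = mode, profile = profile,
                 initial = state0$amounts, omega = omega, seed = seed,
                 times = times, mass_leak = leak),
            class = "gt_sim")
}

integrate_deterministic <- function(y0, net, times) {
  r1 <- net$r1; r2 <- net$r2; k <- net$k; S <- net$S
  deriv <- function(t, y, parms) {
    y2 <- c(1, pmax(y, 0))
    flux <- k * y2[r1 + 1L] * y2[r2 + 1L]
    list(as.vector(S %*% flux))
  }
  out <- deSolve::lsoda(y = y0, times = times, func = deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  unname(as.matrix(out))
}

run_gillespie <- function(y0, net, times, seed = NULL, omega = 1) {
  if (!is.null(seed)) set.seed(seed)
  assert_scalar_num(omega, "omega", positive = TRUE)
  n <- round(y0)
  r1 <- net$r1; r2 <- net$r2
  # fold omega into bilinear rate constants
  k <- ifelse(r2 > 0L, net$k / omega, net$k)
  S <- net$S
  m <- length(k)
  out <- matrix(0, nrow = length(times), ncol = length(n) + 1L)
  out[, 1] <- times
  t_now <- 0
  next_out <- 1L
  repeat {
    while (next_out <= length(times) && times[next_out] <= t_now + 1e-15) {
      out[next_out, -1] <- n
      next_out <- next_out + 1L
    }
    if (next_out > length(times)) break
    n2 <- c(1, n)
    a <- k * n2[r1 + 1L] * n2[r2 + 1L]
    a0 <- sum(a)
    if (a0 <= 0) {
      while (next_out <= length(times)) {
        out[next_out, -1] <- n
        next_out <- next_out + 1L
      }
      break
    }
    t_now <- t_now + stats::rexp(1, a0)
    if (t_now > times[length(times)]) {
      while (next_out <= length(times)) {
        out[next_out, -1] <- n
        next_out <- next_out + 1L
      }
      break
    }
    j <- sample.int(m, 1L, prob = a)
    n <- n + S[, j]
  }
  out
}

#' Ranked product profile at a time point
#'
#' Species amounts at the output step nearest `at_time`, excluding enzyme
#' intermediates and the remaining substrate(s), sorted descending, with
#' fractional composition over the products.
#'
#' @param result A `gt_sim` from [simulate_disproportionation()].
#' @param at_time Time, minutes, within the simulated range.
#' @param exclude Species to exclude as "remaining substrate"; defaults to
#'   the species that started with a nonzero amount.
#' @return Tibble `species`, `amount`, `fraction`, sorted by amount.
#' @export
product_profile <- function(result, at_time, exclude = NULL) {
  if (!inherits(result, "gt_sim")) stop_gt("Not a simulation result.", "gt_validation_error")
  tt <- unique(result$trajectory$time)
  if (at_time < min(tt) - 1e-9 || at_time > max(tt) + 1e-9) {
    stop_gt("at_time is outside the simulated range.", "gt_validation_error")
  }
  t_near <- tt[which.min(abs(tt - at_time))]
  exclude <- exclude %||% names(result$initial[result$initial > 0])
  prof <- result$trajectory |>
    dplyr::filter(.data$time == t_near, .data$kind == "free",
                  !.data$species %in% exclude, .data$amount > 0) |>
    dplyr::select("species", "amount") |>
    dplyr::arrange(dplyr::desc(.data$amount))
  tot <- sum(prof$amount)
  prof$fraction <- if (tot > 0) prof$amount / tot else rep(0, nrow(prof))
  prof
}

#' Glucose-unit totals over a simulated trajectory
#'
#' @param result A `gt_sim`.
#' @return Tibble `time`, `total_units` (free species plus enzyme-held
#'   fragments, weighted by length).
#' @export
glucan_unit_totals <- function(result) {
  units <- stats::setNames(result$units, result$species)
  result$trajectory |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(total_units = sum(.data$amount * units[.data$species]),
                     .groups = "drop")
}

#' @export
print.gt_sim <- function(x, ...) {
  cat(sprintf("Disproportionation simulation (%s, %s preset): %d species, t = 0-%g min\n",
              x$mode, x$profile$name, length(x$species), max(x$times)))
  invisible(x)
}

#' @export
tidy.gt_sim <- function(x, ...) x$trajectory

#' @export
glance.gt_sim <- function(x, ...) {
  tibble::tibble(mode = x$mode, preset = x$profile$name,
                 n_species = length(x$species), t_max = max(x$times),
                 mass_leak = x$mass_leak)
}

#' @export
autoplot.gt_sim <- function(object, max_species = 8, ...) {
  top <- object$trajectory |>
    dplyr::filter(.data$kind == "free") |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(peak = max(.data$amount), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$peak)) |>
    dplyr::slice_head(n = max_species)
  object$trajectory |>
    dplyr::filter(.data$species %in% top$species) |>
    ggplot2::ggplot(ggplot2::aes(.data$time, .data$amount, colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "amount",
                  title = sprintf("Disproportionation (%s)", object$profile$name)) +
    ggplot2::theme_minimal()
}
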