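# Network solvers. Phasor convention: a signal x(t) = X_amp sin(w t + phi)
# is represented by the complex phasor X = X_amp * exp(1i * phi), i.e.
# x(t) = Im(X * exp(1i * w * t)). Differentiation maps to multiplication by
# 1i * w, so element admittances are G = 1/R and 1i * w * C as usual.

.element_admittance <- function(elements, omega) {
  ifelse(elements$kind == "R", 1 / elements$value,
         1i * omega * elements$value + 0i)
}

# Complex nodal admittance matrix over the non-ground nodes.
.admittance_matrix <- function(network, omega) {
  nodes <- network$nodes
  k <- length(nodes)
  idx <- stats::setNames(seq_len(k), nodes)
  Y <- matrix(0 + 0i, k, k, dimnames = list(nodes, nodes))
  y <- .element_admittance(network$elements, omega)
  ia <- idx[network$elements$node_a]
  ib <- idx[network$elements$node_b]
  for (e in seq_along(y)) {
    a <- ia[e]; b <- ib[e]
    if (!is.na(a)) Y[a, a] <- Y[a, a] + y[e]
    if (!is.na(b)) Y[b, b] <- Y[b, b] + y[e]
    if (!is.na(a) && !is.na(b)) {
      Y[a, b] <- Y[a, b] - y[e]
      Y[b, a] <- Y[b, a] - y[e]
    }
  }
  Y
}

#' Solve the network in sinusoidal steady state
#'
#' Complex nodal analysis at the drive frequency: the ideal source pins the
#' source node to the drive phasor `amplitude * exp(1i * phase)` and the
#' remaining node voltages solve `Y v = i`. Branch currents follow from
#' node-voltage differences and element admittances.
#'
#' @param network A [circuit_network()].
#' @param drive A [drive_config()].
#' @return An object of class `phasor_solution`: a list with `node_voltage`
#'   (named complex vector incl. ground = 0), `branches` (the element tibble
#'   plus complex `current` flowing node_a -> node_b), `source_current`
#'   (complex phasor of the current delivered by the source), `frequency`,
#'   and `residual` (relative KCL residual of the solve).
#' @export
solve_phasor <- function(network, drive = drive_config()) {
  omega <- 2 * pi * drive$frequency
  nodes <- network$nodes
  Y <- .admittance_matrix(network, omega)
  s <- match(network$source_node, nodes)
  vs <- drive$amplitude * exp(1i * drive$phase)
  free <- setdiff(seq_along(nodes), s)
  v <- stats::setNames(rep(0 + 0i, length(nodes)), nodes)
  v[s] <- vs
  if (length(free) > 0 && drive$amplitude > 0) {
    rhs <- -Y[free, s, drop = FALSE] * vs
    Yff <- Y[free, free, drop = FALSE]
    sol <- tryCatch(solve(Yff, rhs),
                    error = function(e) {
                      stop("solve_phasor: singular admittance matrix; ",
                           "check for a floating subgraph (",
                           conditionMessage(e), ")", call. = FALSE)
                    })
    # one step of iterative refinement: the element values span ~15 orders
    # of magnitude, and this recovers the last digits of the nodal solve
    sol <- sol + solve(Yff, rhs - Yff %*% sol)
    v[free] <- sol[, 1]
  }
  # KCL residual at non-source nodes, relative to the source current
  resid_vec <- Y %*% v
  residual <- if (length(free) > 0 && drive$amplitude > 0) {
    max(Mod(resid_vec[free])) / max(Mod(resid_vec[s]), 1e-300)
  } else 0
  vfull <- c(v, stats::setNames(0 + 0i, network$ground_node))
  el <- network$elements
  y <- .element_admittance(el, omega)
  branches <- dplyr::mutate(el,
    current = unname((vfull[el$node_a] - vfull[el$node_b]) * y))
  inc_a <- branches$current[branches$node_a == network$source_node]
  inc_b <- branches$current[branches$node_b == network$source_node]
  source_current <- sum(inc_a) - sum(inc_b)
  structure(list(node_voltage = vfull, branches = branches,
                 source_current = source_current,
                 frequency = drive$frequency, omega = omega,
                 amplitude = drive$amplitude, phase = drive$phase,
                 residual = residual),
            class = "phasor_solution")
}

#' @export
print.phasor_solution <- function(x, ...) {
  cat("<phasor_solution> ", length(x$node_voltage) - 1, " nodes at ",
      x$frequency / 1e3, " kHz; |I_source| = ",
      format(Mod(x$source_current), digits = 4), " A\n", sep = "")
  invisible(x)
}

#' Tidy a phasor solution into a per-branch tibble
#'
#' @param x A `phasor_solution`.
#' @param ... Unused.
#' @return A tibble with `label`, `kind`, `value`, `node_a`, `node_b`,
#'   `amplitude` (A) and `phase` (rad) of each branch current.
#' @method tidy phasor_solution
#' @export
tidy.phasor_solution <- function(x, ...) {
  dplyr::transmute(x$branches,
    label = .data$label, kind = .data$kind, value = .data$value,
    node_a = .data$node_a, node_b = .data$node_b,
    amplitude = Mod(.data$current), phase = Arg(.data$current))
}

#' Brute-force transient simulation of the network
#'
#' Trapezoidal (A-stable, second order) time integration from a fully
#' discharged initial state, with the source node forced to
#' `amplitude * sin(w t + phase)`. This is deliberately independent of the
#' phasor path and serves as its oracle: after start-up transients decay,
#' per-cycle waveforms must match the phasor solution.
#'
#' @param network A [circuit_network()].
#' @param drive A [drive_config()].
#' @param dt Time step (s). Should resolve the drive with at least 200 steps
#'   per cycle; coarser steps trigger a warning.
#' @param t_end End time (s).
#' @return An object of class `transient_solution`: `time` (vector),
#'   `node_voltage` (matrix, nodes x steps, incl. ground row), `frequency`.
#' @export
solve_transient <- function(network, drive = drive_config(), dt, t_end) {
  if (dt <= 0 || t_end <= dt) stop("solve_transient: need 0 < dt < t_end",
                                   call. = FALSE)
  period <- 1 / drive$frequency
  if (dt > period / 200) {
    warning(sprintf(paste0("solve_transient: dt = %.3g s gives only %.0f steps",
                           " per cycle (< 200); expect amplitude errors of",
                           " order %.1g relative"),
                    dt, period / dt, (2 * pi * dt / period)^2 / 12))
  }
  omega <- 2 * pi * drive$frequency
  nodes <- network$nodes
  k <- length(nodes)
  idx <- stats::setNames(seq_len(k), nodes)
  G <- matrix(0, k, k, dimnames = list(nodes, nodes))
  Cm <- matrix(0, k, k, dimnames = list(nodes, nodes))
  el <- network$elements
  for (e in seq_len(nrow(el))) {
    a <- idx[el$node_a[e]]; b <- idx[el$node_b[e]]
    M <- if (el$kind[e] == "R") 1 / el$value[e] else el$value[e]
    tgt <- if (el$kind[e] == "R") "G" else "C"
    add <- function(mat) {
      if (!is.na(a)) mat[a, a] <- mat[a, a] + M
      if (!is.na(b)) mat[b, b] <- mat[b, b] + M
      if (!is.na(a) && !is.na(b)) {
        mat[a, b] <- mat[a, b] - M
        mat[b, a] <- mat[b, a] - M
      }
      mat
    }
    if (tgt == "G") G <- add(G) else Cm <- add(Cm)
  }
  s <- idx[[network$source_node]]
  free <- setdiff(seq_len(k), s)
  times <- seq(0, t_end, by = dt)
  nst <- length(times)
  vsrc <- drive$amplitude * sin(omega * times + drive$phase)
  V <- matrix(0, k, nst, dimnames = list(nodes, NULL))
  V[s, ] <- vsrc
  Grr <- G[free, free, drop = FALSE]; Crr <- Cm[free, free, drop = FALSE]
  Grs <- G[free, s, drop = TRUE];     Crs <- Cm[free, s, drop = TRUE]
  lhs <- Crr / dt + Grr / 2
  lhs_inv <- tryCatch(solve(lhs), error = function(e) {
    stop("solve_transient: singular system (floating subgraph?)", call. = FALSE)
  })
  rhs_mat <- Crr / dt - Grr / 2
  step_mat <- lhs_inv %*% rhs_mat
  for (kk in 2:nst) {
    forcing <- -Crs * (vsrc[kk] - vsrc[kk - 1]) / dt -
      Grs * (vsrc[kk] + vsrc[kk - 1]) / 2
    V[free, kk] <- step_mat %*% V[free, kk - 1] + lhs_inv %*% forcing
  }
  Vfull <- rbind(V, 0)
  rownames(Vfull) <- c(nodes, network$ground_node)
  structure(list(time = times, node_voltage = Vfull,
                 frequency = drive$frequency, dt = dt),
            class = "transient_solution")
}

#' Branch-current time series from a transient solution
#'
#' Resistor currents are exact node-voltage differences over R; capacitor
#' currents use a centred finite-difference derivative (one-sided at the
#' ends), which is second-order accurate.
#'
#' @param solution A `transient_solution`.
#' @param network The network it was solved on.
#' @return A matrix (elements x time steps) of currents node_a -> node_b,
#'   rownames = element labels.
#' @export
transient_branch_currents <- function(solution, network) {
  V <- solution$node_voltage
  el <- network$elements
  dv <- V[el$node_a, , drop = FALSE] - V[el$node_b, , drop = FALSE]
  out <- matrix(0, nrow(el), ncol(V), dimnames = list(el$label, NULL))
  isR <- el$kind == "R"
  out[isR, ] <- dv[isR, , drop = FALSE] / el$value[isR]
  if (any(!isR)) {
    dt <- solution$dt
    ddt <- function(x) {
      n <- length(x)
      d <- numeric(n)
      d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
      d[1] <- (x[2] - x[1]) / dt
      d[n] <- (x[n] - x[n - 1]) / dt
      d
    }
    ci <- which(!isR)
    for (e in ci) out[e, ] <- el$value[e] * ddt(dv[e, ])
  }
  out
}

#' Extract the fundamental-frequency phasor from a sampled waveform
#'
#' Projects a time series onto `exp(-1i w t)` over an integer number of
#' cycles and returns the phasor in this package's sin convention
#' (`x(t) = Im(X exp(1i w t))`). Used to compare transient cycles against
#' the phasor solution.
#'
#' @param x Sampled signal.
#' @param times Sample times (uniform grid).
#' @param frequency Frequency to project on (Hz). The window `[times[1],
#'   times[length(times)])` should span an integer number of periods.
#' @return A complex phasor; `Mod` is the amplitude, `Arg` the sin-phase.
#' @export
extract_phasor <- function(x, times, frequency) {
  omega <- 2 * pi * frequency
  n <- length(x)
  # drop the final point if it duplicates the start of the next period
  span <- times[n] - times[1]
  n_per <- span * frequency
  if (abs(n_per - round(n_per)) < 1e-6) {
    x <- x[-n]; times <- times[-n]; n <- n - 1L
  }
  1i * (2 / n) * sum(x * exp(-1i * omega * times))
}

#' Audit power balance of a phasor solution
#'
#' In sinusoidal steady state the time-averaged power delivered by the
#' source, `0.5 * Re(V conj(I))`, must equal the total resistive dissipation
#' `sum 0.5 |I_R|^2 R`; capacitors average to zero. This is the solver's
#' conservation check.
#'
#' @param solution A `phasor_solution`.
#' @param network The network it was solved on.
#' @return A one-row tibble: `source_power_W`, `resistive_power_W`,
#'   `capacitive_power_W`, `relative_error`.
#' @export
power_audit <- function(solution, network) {
  vs <- unname(solution$node_voltage[network$source_node])
  p_src <- 0.5 * Re(vs * Conj(solution$source_current))
  br <- solution$branches
  isR <- br$kind == "R"
  p_res <- sum(0.5 * Mod(br$current[isR])^2 * br$value[isR])
  vdiff <- solution$node_voltage[br$node_a] - solution$node_voltage[br$node_b]
  p_cap <- sum(0.5 * Re(vdiff[!isR] * Conj(br$current[!isR])))
  tibble::tibble(
    source_power_W = p_src,
    resistive_power_W = p_res,
    capacitive_power_W = p_cap,
    relative_error = abs(p_src - p_res) / max(abs(p_src), 1e-300)
  )
}

#' Dump a phasor solution as CSV (per-branch amplitude and phase)
#'
#' @param solution A `phasor_solution`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(solution, path) {
  readr::write_csv(tidy.phasor_solution(solution), path)
  invisible(path)
}
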