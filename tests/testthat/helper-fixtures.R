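# Shared fixtures: the default pipeline is solved once per test run, and a
# few hand-made networks / independent oracles are provided for cross-checks.

.fixture_env <- new.env(parent = emptyenv())

pd_pipeline <- function() {
  if (is.null(.fixture_env$pip)) .fixture_env$pip <- plasma_dose_field()
  .fixture_env$pip
}

# single resistor from the source straight to ground
toy_single_r <- function(R = 100) {
  circuit_network(
    tibble::tibble(label = "R1", kind = "R", value = R,
                   node_a = "S", node_b = "GND"),
    source_node = "S")
}

# series RC divider: source -- R -- node N -- C -- ground
toy_series_rc <- function(R = 1e3, C = 10e-9) {
  circuit_network(
    tibble::tibble(label = c("R1", "C1"), kind = c("R", "C"),
                   value = c(R, C),
                   node_a = c("S", "N"), node_b = c("N", "GND")),
    source_node = "S")
}

# pure capacitor to ground (lossless)
toy_single_c <- function(C = 1e-9) {
  circuit_network(
    tibble::tibble(label = "C1", kind = "C", value = C,
                   node_a = "S", node_b = "GND"),
    source_node = "S")
}

# Three-region miniature of the full ladder topology, values picked at the
# scale of the real network so the solvers face similar conditioning. Nodes
# per region: B (buffer top), U (buffer/cell), M (cyt top), Q (cyt bottom),
# D (cell/dish); ground shared. 15 nodes + ground.
toy_three_ladder <- function() {
  n <- 1:3
  rows <- dplyr::bind_rows(
    tibble::tibble(label = paste0("Rbufv", n), kind = "R",
                   value = c(3e5, 1e5, 5e4),
                   node_a = paste0("B", n), node_b = paste0("U", n)),
    tibble::tibble(label = paste0("Cmemt", n), kind = "C",
                   value = c(1e-11, 3e-11, 6e-11),
                   node_a = paste0("U", n), node_b = paste0("M", n)),
    tibble::tibble(label = paste0("Rcytv", n), kind = "R",
                   value = c(5e3, 2e3, 1e3),
                   node_a = paste0("M", n), node_b = paste0("Q", n)),
    tibble::tibble(label = paste0("Ccytv", n), kind = "C",
                   value = c(5e-13, 1.5e-12, 3e-12),
                   node_a = paste0("M", n), node_b = paste0("Q", n)),
    tibble::tibble(label = paste0("Cmemb", n), kind = "C",
                   value = c(1e-11, 3e-11, 6e-11),
                   node_a = paste0("Q", n), node_b = paste0("D", n)),
    tibble::tibble(label = paste0("Cdish", n), kind = "C",
                   value = c(1e-17, 3e-17, 6e-17),
                   node_a = paste0("D", n), node_b = "GND"),
    tibble::tibble(label = paste0("Rbufr", 1:2), kind = "R",
                   value = c(1e4, 8e3),
                   node_a = paste0("B", 1:2), node_b = paste0("B", 2:3)),
    tibble::tibble(label = paste0("Rcytr", 1:2), kind = "R",
                   value = c(2e4, 1.5e4),
                   node_a = paste0("M", 1:2), node_b = paste0("M", 2:3))
  )
  circuit_network(rows, source_node = "B1")
}

# a hand-made dose field with prescribed phasors (sigma = 1, 20 kHz)
synthetic_field <- function(Jr, Jz, sigma = 1, frequency = 20e3) {
  field <- tibble::tibble(
    region = seq_along(Jr),
    center_radius = seq_along(Jr) * 1e-4,
    Jr = as.complex(Jr), Jz = as.complex(Jz),
    J_amp = sqrt(Mod(Jr)^2 + Mod(Jz)^2),
    pbar = (Mod(Jr)^2 + Mod(Jz)^2) / (2 * sigma),
    p_peak = NA_real_
  )
  structure(field, class = c("dose_field", class(field)),
            sigma = sigma, frequency = frequency, phase = 0)
}

# Independent brute-force oracle: dense time integration of the gated power
# of one region from t = 0, no cycle decomposition, no interpolation.
# Thresholds in SI. Returns the first crossing time, or Inf.
oracle_tstar <- function(field, n, pth_si, wth_si, t_max, spc = 512) {
  f <- attr(field, "frequency")
  sigma <- attr(field, "sigma")
  dtt <- 1 / (f * spc)
  t <- seq(0, t_max, by = dtt)
  i <- match(n, field$region)
  jr <- Mod(field$Jr[i]) * sin(2 * pi * f * t + Arg(field$Jr[i]))
  jz <- Mod(field$Jz[i]) * sin(2 * pi * f * t + Arg(field$Jz[i]))
  p <- (jr^2 + jz^2) / sigma
  g <- p * (p >= pth_si)
  cum <- c(0, cumsum((g[-1] + g[-length(g)]) / 2 * dtt))
  j <- which(cum >= wth_si)[1]
  if (is.na(j)) return(Inf)
  t[j]
}

# brute-force death radius: outermost region whose oracle crossing time is
# within tp, reported at that region's centre (no interpolation)
oracle_death_radius <- function(field, pth_si, wth_si, tp, spc = 512) {
  tstar <- vapply(field$region, function(n) {
    oracle_tstar(field, n, pth_si, wth_si, t_max = tp * 1.01, spc = spc)
  }, numeric(1))
  dead <- tstar <= tp
  if (!any(dead)) return(0)
  field$center_radius[max(which(dead))]
}
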