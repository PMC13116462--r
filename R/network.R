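# Circuit construction for the equivalent-circuit network (EECN).
#
# Each of the 40 annular regions carries a vertical ladder from the liquid
# surface to the grounded plate:
#
#   buffer-top (B)  --R_buffer-->  buffer/cell interface (U)
#                   --C_membrane(top)-->   cytoplasm top (M)
#                   --R_cyt || C_cyt-->    cytoplasm bottom (Q)
#                   --C_membrane(bottom)-> cell/dish interface (D)
#                   --C_dish-->            ground
#
# Adjacent regions are linked by radial resistors within the two conducting
# layers (buffer and cytoplasm). The plasma channel is treated as a perfect
# conductor, so the ideal source drives the buffer-top node of region 1
# only; buffer-top nodes of regions 2..40 see nothing above them (air).
# All dish-bottom terminals share the grounded copper plate.

#' Compute R/C element values for every mesh region
#'
#' Vertical elements use the plate formulas `R = H / (sigma * A)` and
#' `C = eps * A / thickness` on each region's annulus area. Radial elements
#' between adjacent region centres use the annular-log resistance
#' `ln(r_outer_center / r_inner_center) / (2 * pi * sigma * H)`, which is
#' exact for purely radial flow through an annular shell of height `H`.
#'
#' A layer with zero conductivity contributes no resistive element (open
#' circuit): the membrane is capacitive only under the default
#' `membrane_conductivity = 0`.
#'
#' @param mesh A [build_mesh()] result.
#' @param geometry A [geometry_config()].
#' @param materials A [material_config()].
#' @return A list of class `element_set` with tibbles `vertical` (per region:
#'   `buffer_R`, `membrane_C`, `membrane_R` (NA when non-conducting),
#'   `cytoplasm_R`, `cytoplasm_C`, `dish_C`) and `radial` (per interior
#'   boundary: `boundary`, `boundary_radius`, `buffer_R`, `cytoplasm_R`),
#'   all values in ohms / farads.
#' @export
element_values <- function(mesh, geometry, materials) {
  A <- mesh$annulus_area
  g <- geometry
  m <- materials
  vertical <- tibble::tibble(
    region = mesh$region,
    buffer_R = g$buffer_height / (m$buffer_conductivity * A),
    membrane_C = m$membrane_permittivity * A / g$membrane_thickness,
    membrane_R = if (m$membrane_conductivity > 0) {
      g$membrane_thickness / (m$membrane_conductivity * A)
    } else NA_real_,
    cytoplasm_R = g$cell_height / (m$cytoplasm_conductivity * A),
    cytoplasm_C = m$cytoplasm_permittivity * A / g$cell_height,
    dish_C = m$dish_permittivity * A / g$dish_height
  )
  cr <- mesh$center_radius
  lr <- log(cr[-1] / cr[-40])
  radial <- tibble::tibble(
    boundary = 1:39,
    boundary_radius = mesh$outer_radius[1:39],
    buffer_R = lr / (2 * pi * m$buffer_conductivity * g$buffer_height),
    cytoplasm_R = lr / (2 * pi * m$cytoplasm_conductivity * g$cell_height)
  )
  structure(list(vertical = vertical, radial = radial,
                 cell_height = g$cell_height),
            class = "element_set")
}

#' Construct a circuit network from an element table
#'
#' Low-level constructor used both by [assemble_network()] and by tests that
#' build small hand-made networks. The solver and netlist writer operate on
#' this representation.
#'
#' @param elements A data frame with columns `label` (unique, starting with
#'   "R" or "C"), `kind` ("R" or "C"), `value` (ohms or farads, positive),
#'   `node_a`, `node_b` (node names; use `ground_node` for ground).
#' @param source_node Name of the node the ideal voltage source drives.
#' @param ground_node Name of the ground node (default "GND").
#' @return An object of class `circuit_network`.
#' @export
circuit_network <- function(elements, source_node, ground_node = "GND") {
  elements <- tibble::as_tibble(elements)
  needed <- c("label", "kind", "value", "node_a", "node_b")
  if (!all(needed %in% names(elements))) {
    stop("circuit_network: `elements` needs columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(elements$label)) {
    stop("circuit_network: element labels must be unique", call. = FALSE)
  }
  if (!all(elements$kind %in% c("R", "C"))) {
    stop("circuit_network: `kind` must be \"R\" or \"C\"", call. = FALSE)
  }
  if (any(!is.finite(elements$value)) || any(elements$value <= 0)) {
    stop("circuit_network: element values must be positive and finite",
         call. = FALSE)
  }
  nodes <- unique(c(elements$node_a, elements$node_b, source_node, ground_node))
  if (!source_node %in% nodes || identical(source_node, ground_node)) {
    stop("circuit_network: invalid source node", call. = FALSE)
  }
  net <- structure(list(elements = elements,
                        nodes = setdiff(nodes, ground_node),
                        source_node = source_node,
                        ground_node = ground_node),
                   class = "circuit_network")
  floating <- .unreachable_nodes(net)
  if (length(floating) > 0) {
    stop("circuit_network: floating subgraph not connected to source/ground: ",
         paste(floating, collapse = ", "), call. = FALSE)
  }
  net
}

# Nodes not reachable from {source, ground} walking element edges.
.unreachable_nodes <- function(network) {
  all_nodes <- c(network$nodes, network$ground_node)
  adj <- split(c(network$elements$node_b, network$elements$node_a),
               c(network$elements$node_a, network$elements$node_b))
  seen <- stats::setNames(rep(FALSE, length(all_nodes)), all_nodes)
  queue <- c(network$source_node, network$ground_node)
  seen[queue] <- TRUE
  while (length(queue) > 0) {
    nb <- unique(unlist(adj[queue], use.names = FALSE))
    queue <- nb[!seen[nb]]
    seen[queue] <- TRUE
  }
  names(seen)[!seen]
}

#' Assemble the full EECN for the 40-region well
#'
#' Builds the ladder-plus-radial-links topology described in this file's
#' header: 40 vertical ladders (buffer resistance, top membrane capacitance,
#' cytoplasm R parallel C, bottom membrane capacitance, dish capacitance to
#' ground), 39 radial buffer resistors between adjacent buffer-top nodes and
#' 39 radial cytoplasm resistors between adjacent cytoplasm-top nodes. The
#' ideal sinusoidal source attaches to the buffer-top node of region 1.
#'
#' @param elements An [element_values()] result.
#' @param mesh The [build_mesh()] mesh the elements were computed on.
#' @param drive A [drive_config()]; recorded on the network for export.
#' @return A `circuit_network` whose element labels encode layer and region
#'   (e.g. `Rcytv12` = vertical cytoplasm resistor of region 12, `Rcytr5` =
#'   radial cytoplasm resistor across boundary 5|6).
#' @export
assemble_network <- function(elements, mesh, drive = drive_config()) {
  if (!inherits(elements, "element_set")) {
    stop("assemble_network: `elements` must come from element_values()",
         call. = FALSE)
  }
  v <- elements$vertical
  r <- elements$radial
  n <- v$region
  B <- paste0("B", n); U <- paste0("U", n); M <- paste0("M", n)
  Q <- paste0("Q", n); D <- paste0("D", n)
  rows <- list(
    tibble::tibble(label = paste0("Rbufv", n), kind = "R", value = v$buffer_R,
                   node_a = B, node_b = U),
    tibble::tibble(label = paste0("Cmemt", n), kind = "C", value = v$membrane_C,
                   node_a = U, node_b = M),
    tibble::tibble(label = paste0("Rcytv", n), kind = "R", value = v$cytoplasm_R,
                   node_a = M, node_b = Q),
    tibble::tibble(label = paste0("Ccytv", n), kind = "C", value = v$cytoplasm_C,
                   node_a = M, node_b = Q),
    tibble::tibble(label = paste0("Cmemb", n), kind = "C", value = v$membrane_C,
                   node_a = Q, node_b = D),
    tibble::tibble(label = paste0("Cdish", n), kind = "C", value = v$dish_C,
                   node_a = D, node_b = "GND")
  )
  if (!all(is.na(v$membrane_R))) {
    rows <- c(rows, list(
      tibble::tibble(label = paste0("Rmemt", n), kind = "R", value = v$membrane_R,
                     node_a = U, node_b = M),
      tibble::tibble(label = paste0("Rmemb", n), kind = "R", value = v$membrane_R,
                     node_a = Q, node_b = D)
    ))
  }
  b <- r$boundary
  rows <- c(rows, list(
    tibble::tibble(label = paste0("Rbufr", b), kind = "R", value = r$buffer_R,
                   node_a = paste0("B", b), node_b = paste0("B", b + 1)),
    tibble::tibble(label = paste0("Rcytr", b), kind = "R", value = r$cytoplasm_R,
                   node_a = paste0("M", b), node_b = paste0("M", b + 1))
  ))
  net <- circuit_network(dplyr::bind_rows(rows), source_node = "B1")
  net$drive <- drive
  net$n_regions <- length(n)
  net$boundary_radius <- r$boundary_radius
  net$cell_height <- elements$cell_height
  net
}

#' @export
print.circuit_network <- function(x, ...) {
  cat("<circuit_network> ", length(x$nodes), " nodes (+ ground), ",
      nrow(x$elements), " elements; source at ", x$source_node, "\n", sep = "")
  invisible(x)
}

#' Dump the network's element table as CSV
#'
#' One row per circuit element: label, kind (R or C), value and unit
#' (ohm / farad), and the node pair.
#'
#' @param network A `circuit_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_elements_csv <- function(network, path) {
  el <- network$elements
  out <- tibble::tibble(
    label = el$label, kind = el$kind, value = el$value,
    unit = ifelse(el$kind == "R", "ohm", "farad"),
    node_a = el$node_a, node_b = el$node_b
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Export a SPICE netlist for the network
#'
#' Writes R/C cards plus a SIN voltage source so the network can be re-run
#' in any SPICE-class simulator as an external cross-check of the native
#' solver. Ground is node `0`; other node names are kept verbatim.
#'
#' @param network A `circuit_network`.
#' @param drive A [drive_config()].
#' @param path Optional file to write to.
#' @return The netlist as a character vector of lines (invisibly if `path`
#'   is given).
#' @export
export_netlist <- function(network, drive = drive_config(), path = NULL) {
  nm <- function(x) ifelse(x == network$ground_node, "0", x)
  el <- network$elements
  cards <- sprintf("%s %s %s %.12g", el$label, nm(el$node_a), nm(el$node_b),
                   el$value)
  phase_deg <- drive$phase * 180 / pi
  src <- sprintf("V1 %s 0 SIN(0 %.12g %.12g 0 0 %.12g)",
                 nm(network$source_node), drive$amplitude, drive$frequency,
                 phase_deg)
  lines <- c("* plasmadose equivalent-circuit network", src, cards, ".end")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
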