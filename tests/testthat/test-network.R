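cfg <- default_config()

test_that("element values follow the plate and annular-log formulas", {
  mesh <- build_mesh(cfg$geometry)
  els <- element_values(mesh, cfg$geometry, cfg$materials)
  v <- els$vertical
  # worked examples on a 1 mm2 area
  expect_equal(1e-4 / (0.172 * 1e-6), 581.3953, tolerance = 1e-6)
  expect_equal(5 * vacuum_permittivity() * 1e-6 / 7.5e-9, 5.9028e-9,
               tolerance = 1e-4)
  expect_equal(2.4 * vacuum_permittivity() * 1e-6 / 1.5e-3, 1.417e-14,
               tolerance = 1e-3)
  # area scaling: R * A and C / A are layer constants
  expect_equal(v$buffer_R * mesh$annulus_area,
               rep(cfg$geometry$buffer_height / cfg$materials$buffer_conductivity, 40))
  expect_equal(v$dish_C / mesh$annulus_area,
               rep(cfg$materials$dish_permittivity / cfg$geometry$dish_height, 40))
  expect_true(all(v$cytoplasm_R > 0) && all(v$membrane_C > 0))
  expect_true(all(is.na(v$membrane_R)))  # insulating membrane: open circuit
  # doubling the buffer conductivity halves every buffer resistance
  mat2 <- material_config(buffer_conductivity = 2 * cfg$materials$buffer_conductivity)
  els2 <- element_values(mesh, cfg$geometry, mat2)
  expect_equal(els2$vertical$buffer_R, v$buffer_R / 2)
  expect_equal(els2$radial$buffer_R, els$radial$buffer_R / 2)
})

test_that("annular-log radial resistance converges to the thin-shell limit", {
  mesh <- build_mesh(cfg$geometry)
  els <- element_values(mesh, cfg$geometry, cfg$materials)
  cr <- mesh$center_radius
  # outer boundaries: dr/r is small, log formula ~ dr / (sigma 2 pi r_mid H)
  for (b in 25:34) {
    dr <- cr[b + 1] - cr[b]
    r_mid <- (cr[b + 1] + cr[b]) / 2
    approx_R <- dr / (cfg$materials$buffer_conductivity * 2 * pi * r_mid *
                        cfg$geometry$buffer_height)
    expect_equal(els$radial$buffer_R[b], approx_R, tolerance = 0.01)
  }
})

test_that("assembled network has the ladder-plus-radial-links topology", {
  pip <- pd_pipeline()
  el <- pip$network$elements
  counts <- table(sub("[0-9]+$", "", el$label))
  expect_identical(as.integer(counts[c("Rbufv", "Cmemt", "Rcytv", "Ccytv",
                                       "Cmemb", "Cdish")]),
                   rep(40L, 6))
  expect_identical(as.integer(counts[c("Rbufr", "Rcytr")]), rep(39L, 2))
  # node count: 5 nodes per region plus ground; hand enumeration of the
  # 3-region miniature gives 15 + ground, i.e. 5n in both cases
  expect_identical(length(pip$network$nodes), 200L)
  expect_identical(length(toy_three_ladder()$nodes), 15L)
  expect_identical(pip$network$source_node, "B1")
})

test_that("without radial links only the driven ladder carries current", {
  pip <- pd_pipeline()
  el <- pip$network$elements
  cut <- el[!grepl("^R(buf|cyt)r", el$label), ]
  net <- circuit_network(cut, source_node = "B1")
  sol <- solve_phasor(net, cfg$drive)
  i2 <- Mod(sol$branches$current[sol$branches$label == "Rbufv2"])
  i1 <- Mod(sol$branches$current[sol$branches$label == "Rbufv1"])
  expect_gt(i1, 0)
  expect_lt(i2, i1 * 1e-12)
})

test_that("floating subgraphs are rejected by name", {
  el <- tibble::tibble(label = c("R1", "R2"), kind = "R", value = c(1, 1),
                       node_a = c("S", "X"), node_b = c("GND", "Y"))
  expect_error(circuit_network(el, source_node = "S"), "X|Y")
  expect_error(circuit_network(
    tibble::tibble(label = "R1", kind = "R", value = -5,
                   node_a = "S", node_b = "GND"), source_node = "S"),
    "positive")
})

test_that("netlist export emits valid SPICE cards", {
  nl <- export_netlist(toy_single_r(100), cfg$drive)
  expect_length(grep("^V1 ", nl), 1L)
  expect_length(grep("^R1 ", nl), 1L)
  expect_identical(nl[length(nl)], ".end")
  # ground is node 0
  expect_match(nl[grep("^R1", nl)], " 0 ")

  pip <- pd_pipeline()
  nl_full <- export_netlist(pip$network, cfg$drive)
  cards <- grep("^[RCV]", nl_full, value = TRUE)
  expect_identical(length(cards), nrow(pip$network$elements) + 1L)
  # every card is "name node node value..." with a parseable value
  parts <- strsplit(cards[-1], " +")
  expect_true(all(vapply(parts, length, integer(1)) == 4L))
  expect_false(any(is.na(as.numeric(vapply(parts, `[[`, "", 4L)))))
  path <- withr::local_tempfile(fileext = ".cir")
  export_netlist(pip$network, cfg$drive, path)
  expect_true(file.exists(path))
})

test_that("element table dumps with units", {
  pip <- pd_pipeline()
  path <- withr::local_tempfile(fileext = ".csv")
  write_elements_csv(pip$network, path)
  got <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(nrow(got), nrow(pip$network$elements))
  expect_true(all(got$unit[got$kind == "R"] == "ohm"))
  expect_true(all(got$unit[got$kind == "C"] == "farad"))
})
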