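test_that(".topo files parse with inferred node order and round-trip", {
  f <- withr::local_tempfile(fileext = ".topo")
  writeLines(c("ZEB miR200 2", "miR200 ZEB 2"), f)
  topo <- load_topology(f)
  expect_equal(topo$nodes, c("ZEB", "miR200"))
  expect_equal(nrow(topo$edges), 2L)
  expect_true(all(topo$edges$sign == "inhibition"))

  # header tolerated on read, always written on save; canonical round-trip
  out <- withr::local_tempfile(fileext = ".topo")
  save_topology(topo, out)
  expect_identical(readLines(out)[1], "Source Target Type")
  topo2 <- load_topology(out)
  expect_equal(topo2$nodes, topo$nodes)
  expect_equal(topo2$edges, topo$edges)
  # byte-stable: save(load(saved)) reproduces the file
  out2 <- withr::local_tempfile(fileext = ".topo")
  save_topology(topo2, out2)
  expect_identical(readLines(out2), readLines(out))
})

test_that("malformed .topo input is rejected with line context", {
  f <- withr::local_tempfile(fileext = ".topo")
  writeLines(character(0), f)
  expect_error(load_topology(f), "no edges")

  writeLines(c("A B 2", "A B"), f)
  expect_error(load_topology(f), "line 2")

  writeLines(c("A B 3"), f)
  expect_error(load_topology(f), "Type code '3'")

  expect_error(load_topology(file.path(tempdir(), "nope.topo")), "not found")
})

test_that("bundled circuits match their published wiring", {
  circuits <- lapply(
    c("base", "uncoupled", "grhl2", "grhl2_kd", "ovol", "nrf2"),
    builtin_circuit
  )
  names(circuits) <- vapply(circuits, `[[`, "", "name")

  for (topo in circuits) expect_length(validate_topology(topo), 0)

  expect_equal(vapply(circuits, function(t) length(t$nodes), 0L),
               c(base = 6L, uncoupled = 6L, grhl2 = 7L, grhl2_kd = 7L,
                 ovol = 7L, nrf2 = 7L))
  expect_equal(nrow(circuits$base$edges), 14L)

  edge_key <- function(t) paste(t$edges$source, t$edges$target, t$edges$sign)
  # both coupling links present in base, absent in uncoupled
  expect_true(all(c("let7 ZEB inhibition", "miR200 LIN28 inhibition") %in%
                    edge_key(circuits$base)))
  expect_setequal(
    setdiff(edge_key(circuits$base), edge_key(circuits$uncoupled)),
    c("let7 ZEB inhibition", "miR200 LIN28 inhibition")
  )

  # grhl2_kd = grhl2 minus the GRHL2 -> miR200 activation
  expect_setequal(
    setdiff(edge_key(circuits$grhl2), edge_key(circuits$grhl2_kd)),
    "GRHL2 miR200 activation"
  )

  # grhl2_kd and ovol differ only in the PSF self-edge sign (after renaming)
  rename_psf <- function(keys, from, to) gsub(from, to, keys, fixed = TRUE)
  kd <- rename_psf(edge_key(circuits$grhl2_kd), "GRHL2", "PSF")
  ov <- rename_psf(edge_key(circuits$ovol), "OVOL", "PSF")
  expect_setequal(setdiff(kd, ov), "PSF PSF activation")
  expect_setequal(setdiff(ov, kd), "PSF PSF inhibition")

  expect_error(builtin_circuit("grhl3"), "valid names")
})

test_that("validate_topology reports structural violations as diagnostics", {
  base <- builtin_circuit("base")
  expect_length(validate_topology(base), 0)

  dup <- base
  dup$edges <- rbind(dup$edges, dup$edges[2, ])
  d <- validate_topology(dup)
  expect_length(grep("duplicate edge", d), 1)

  bad <- base
  bad$edges$source[1] <- "GHOST"
  d <- validate_topology(bad)
  expect_length(grep("unknown node 'GHOST'", d), 1)

  expect_error(circuit_topology(c("A", "B"), data.frame(
    source = "A", target = "C", sign = "activation")), "unknown node")
})
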