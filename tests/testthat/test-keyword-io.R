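test_that("fixed-width and comma node lines decode to identical records", {
  fixed <- c("*KEYWORD", "*NODE",
             "       7           100.0           200.0           300.0",
             "*END")
  comma <- c("*KEYWORD", "*NODE", "7,100.0,200.0,300.0", "*END")
  loose <- c("*KEYWORD", "*NODE",
             "       7     100.0     200.0     300.0", "*END")
  for (txt in list(fixed, comma, loose)) {
    frag <- parse_keyword_file(txt)
    expect_equal(frag$nodes$id, 7L)
    expect_equal(unlist(frag$nodes[1, c("x", "y", "z")]),
                 c(x = 100, y = 200, z = 300))
  }
})

test_that("duplicate node ids raise an error naming the id", {
  txt <- c("*NODE", "1,0,0,0", "2,1,0,0", "*NODE", "2,2,0,0", "3,3,0,0")
  expect_error(parse_keyword_file(txt), "duplicate node id.*2")
})

test_that("malformed numeric fields report the line number", {
  txt <- c("*NODE", "1,0,0,0", "2,oops,0,0")
  expect_error(parse_keyword_file(txt), "malformed numeric.*line 3")
})

test_that("unknown cards are preserved verbatim and re-emitted unchanged", {
  txt <- c("*KEYWORD", "*MAT_OGDEN_RUBBER", "$ pass-through material",
           "1,1e-6,0.499", "*NODE", "1,0,0,0", "2,1,0,0", "3,0,1,0",
           "4,1,1,0", "*END")
  frag <- parse_keyword_file(txt)
  expect_length(frag$extra, 1)
  expect_equal(frag$extra[[1]]$keyword, "*MAT_OGDEN_RUBBER")
  expect_equal(frag$extra[[1]]$lines,
               c("*MAT_OGDEN_RUBBER", "$ pass-through material",
                 "1,1e-6,0.499"))
  out <- write_keyword_files(frag)
  expect_true(all(frag$extra[[1]]$lines %in% out$main))
})

test_that("include resolution conserves entity counts and provenance", {
  d <- tempfile(); dir.create(d)
  writeLines(c("*KEYWORD", "*INCLUDE", "nodes.k", "*INCLUDE", "parts.k",
               "*END"), file.path(d, "main.k"))
  writeLines(c("*NODE", paste(1:10, 1:10, 0, 0, sep = ",")),
             file.path(d, "nodes.k"))
  writeLines(c("*PART", "p_one", "1,0,1", "*PART", "p_two", "2,0,1",
               "*PART", "p_three", "3,0,1"), file.path(d, "parts.k"))
  asm <- resolve_includes(file.path(d, "main.k"))
  expect_equal(nrow(asm$nodes), 10)
  expect_equal(nrow(asm$parts), 3)
  expect_setequal(unique(asm$nodes$include), "nodes.k")
  expect_setequal(unique(asm$parts$include), "parts.k")
  expect_equal(asm$includes$role[asm$includes$name == "nodes.k"], "nodes")
})

test_that("cyclic and missing includes are reported", {
  d <- tempfile(); dir.create(d)
  writeLines(c("*KEYWORD", "*INCLUDE", "a.k", "*END"),
             file.path(d, "main.k"))
  writeLines(c("*INCLUDE", "a.k"), file.path(d, "a.k"))
  expect_error(resolve_includes(file.path(d, "main.k")), "cyclic include")
  writeLines(c("*INCLUDE", "nowhere.k"), file.path(d, "a.k"))
  expect_error(resolve_includes(file.path(d, "main.k")),
               "missing include.*nowhere.k")
})

test_that("write/read roundtrip reproduces coordinates and topology in both dialects", {
  fx <- get_fixture()
  for (dialect in c("fixed", "comma")) {
    d <- tempfile()
    main <- write_deck(fx$assembly, d, dialect = dialect)
    back <- resolve_includes(main)
    o1 <- order(fx$assembly$nodes$id); o2 <- order(back$nodes$id)
    expect_equal(back$nodes$id[o2], fx$assembly$nodes$id[o1])
    expect_equal(as.matrix(back$nodes[o2, c("x", "y", "z")]),
                 as.matrix(fx$assembly$nodes[o1, c("x", "y", "z")]),
                 ignore_attr = TRUE)
    expect_equal(back$solids[c("id", "part", paste0("n", 1:8))],
                 fx$assembly$solids[c("id", "part", paste0("n", 1:8))],
                 ignore_attr = TRUE)
    expect_equal(back$shells[c("id", "part", paste0("n", 1:4))],
                 fx$assembly$shells[c("id", "part", paste0("n", 1:4))],
                 ignore_attr = TRUE)
    expect_equal(back$parameters, fx$assembly$parameters)
  }
})

test_that("both dialects of the same deck parse to identical assemblies", {
  fx <- get_fixture()
  d1 <- tempfile(); d2 <- tempfile()
  a1 <- resolve_includes(write_deck(fx$assembly, d1, dialect = "fixed"))
  a2 <- resolve_includes(write_deck(fx$assembly, d2, dialect = "comma"))
  expect_equal(a1$nodes, a2$nodes, ignore_attr = TRUE)
  expect_equal(a1$solids, a2$solids, ignore_attr = TRUE)
  expect_equal(a1$parts, a2$parts, ignore_attr = TRUE)
})

test_that("8-digit node ids fit the fixed-width field and 9-digit ids error", {
  mk <- function(id) hbm_assembly(
    nodes = data.frame(id = c(id, 1:7), x = as.numeric(1:8), y = 0, z = 0))
  expect_no_error(write_keyword_files(mk(99999999L)))
  expect_error(write_keyword_files(mk(100000000L)), "overflow")
  expect_no_error(write_keyword_files(mk(100000000L), dialect = "comma"))
})

test_that("variant assembly differs from the base only in node coordinates", {
  fx <- get_fixture()
  tg <- make_fixture_targets(fx, "scaled_male")
  morphed <- morph_derivative(fx$assembly, tg$plan, tg$source, tg$target)
  variant <- assemble_variant(fx$assembly, morphed$nodes,
                              parameters = list(flesh_density_scale = 1.02))
  d <- assembly_diff(fx$assembly, variant)
  expect_true(d$structure_identical)
  expect_gt(d$nodes_moved, 0)
  expect_equal(d$parameters_changed, "flesh_density_scale")
  # identity: base includes + base nodes reproduces the base model
  same <- assemble_variant(fx$assembly, fx$assembly$nodes)
  d0 <- assembly_diff(fx$assembly, same)
  expect_true(d0$structure_identical)
  expect_equal(d0$nodes_moved, 0)
})

test_that("a truncated variant node set errors listing the missing ids", {
  fx <- get_fixture()
  nodes <- fx$assembly$nodes[-(1:3), ]
  expect_error(assemble_variant(fx$assembly, nodes), "missing node id")
})
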