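test_that("embedded fixtures carry the full transcriptions", {
  t1 <- load_fixture("table1")
  expect_identical(nrow(t1$reactions), 13L)
  r1 <- dplyr::filter(t1$reactions, name == "1↔1*_O1H")
  expect_equal(r1$nu_imag, 1150.3)
  expect_equal(r1$ddG_forward, 96.31)
  expect_equal(r1$dG_reaction, 87.11)
  expect_identical(nrow(t1$reference$kinetics), 13L)

  t2 <- load_fixture("table2")
  c1 <- dplyr::filter(t2$contacts, structure_label == "1",
                      donor_label == "O5H", acceptor_label == "O4")
  expect_equal(c1$rho, 0.041)
  expect_equal(c1$d_HB, 1.770)
  expect_equal(c1$angle_AHB, 147.3)
  # reference annotations are carried separately from input fields
  expect_false("ref_energy" %in% names(t2$contacts))
  expect_identical(nrow(t2$reference$contacts), nrow(t2$contacts))
  expect_identical(sum(t2$reference$contacts$flag_inconsistent), 1L)
  expect_error(load_fixture("table3"), "unknown fixture")
})

test_that("barrier bookkeeping holds across the whole reaction fixture", {
  t1 <- load_fixture("table1")
  joined <- dplyr::inner_join(t1$reactions, t1$reference$kinetics,
                              by = "name")
  expect_equal(reverse_barrier(joined$ddG_forward, joined$dG_reaction),
               joined$ddG_reverse, tolerance = 1e-9)
  expect_equal(joined$ddE_forward - joined$dE_reaction, joined$ddE_reverse,
               tolerance = 1e-9)
})

test_that("validation names the offending field and record", {
  rs <- tiny_reaction_set()
  bad <- rs
  bad$reactions$nu_imag[2] <- -3
  expect_error(validate_reaction_set(bad), "nu_imag.*B↔B\\*")
  bad <- rs
  bad$reactions$name[2] <- bad$reactions$name[1]
  expect_error(validate_reaction_set(bad), "duplicated reaction name")
  bad <- rs
  bad$reactions$reactant[1] <- "ghost"
  expect_error(validate_reaction_set(bad), "ghost")
  bad <- rs
  bad$structures$dipole[1] <- -1
  expect_error(validate_reaction_set(bad), "dipole")
  ct <- load_fixture("table2")$contacts
  ct$d_HB[1] <- ct$d_AB[1] + 1
  expect_error(validate_contacts <- reaction_set(contacts = ct), "d_AB")
})

test_that("ascii aliases replace the arrow and asterisks reversibly enough", {
  expect_identical(ascii_name("1↔1*_O1H"), "1__1s_O1H")
  expect_identical(ascii_name("20↔1**_C2'H2"), "20__1ss_C2'H2")
})

test_that("JSON dialect round-trips field-for-field", {
  dir <- withr::local_tempdir()
  for (fx in c("table1", "table2")) {
    rs <- load_fixture(fx)
    path <- file.path(dir, paste0(fx, ".json"))
    write_reaction_set(rs, path)
    expect_reaction_set_equal(read_reaction_set(path), rs)
  }
  # empty set round-trips too
  path <- file.path(dir, "empty.json")
  write_reaction_set(reaction_set(), path)
  rt <- read_reaction_set(path)
  expect_identical(nrow(rt$reactions), 0L)
  expect_identical(nrow(rt$contacts), 0L)
})

test_that("JSON dialect preserves short decimal literals verbatim", {
  path <- withr::local_tempfile(fileext = ".json")
  rs <- load_fixture("table2")
  rs$contacts$rho[1] <- 0.0415
  write_reaction_set(rs, path)
  expect_true(any(grepl("0.0415", readLines(path), fixed = TRUE)))
  expect_equal(read_reaction_set(path)$contacts$rho[1], 0.0415)
})

test_that("TSV dialect round-trips both tables from one stem", {
  dir <- withr::local_tempdir()
  for (fx in c("table1", "table2")) {
    rs <- load_fixture(fx)
    stem <- file.path(dir, fx)
    write_reaction_set(rs, stem, dialect = "tsv")
    expect_true(file.exists(paste0(stem, ".reactions.tsv")))
    expect_true(file.exists(paste0(stem, ".contacts.tsv")))
    expect_reaction_set_equal(read_reaction_set(stem, dialect = "tsv"), rs)
  }
})

test_that("random synthetic sets round-trip through both dialects", {
  dir <- withr::local_tempdir()
  for (seed in c(2, 17, 301)) {
    rs <- generate_reactions(synth_spec(n_reactions = 4, seed = seed))
    json <- file.path(dir, sprintf("s%d.json", seed))
    write_reaction_set(rs, json)
    expect_reaction_set_equal(read_reaction_set(json), rs)
    stem <- file.path(dir, sprintf("s%d", seed))
    write_reaction_set(rs, stem, dialect = "tsv")
    expect_reaction_set_equal(read_reaction_set(stem, dialect = "tsv"), rs)
  }
})

test_that("readers reject malformed files with named failures", {
  dir <- withr::local_tempdir()
  rs <- tiny_reaction_set()
  path <- file.path(dir, "bad.json")
  rs$reactions$nu_imag[1] <- -1150.3
  # bypass construction-time validation to simulate a corrupt file on disk
  doc <- jsonlite::fromJSON(
    {write_rs <- unclass(rs); p <- file.path(dir, "ok.json")
     write_reaction_set(tiny_reaction_set(), p); p},
    simplifyDataFrame = TRUE)
  doc$reactions$nu_imag[1] <- -1150.3
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  expect_error(read_reaction_set(path), "nu_imag")
  # wrong declared units are refused
  doc2 <- doc
  doc2$reactions$nu_imag[1] <- 1150.3
  doc2$units$energy <- "kJ/mol"
  jsonlite::write_json(doc2, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  expect_error(read_reaction_set(path), "kcal/mol")
  expect_error(read_reaction_set(file.path(dir, "absent.json")),
               "no such file")
})

test_that("shipped extdata files load and match the embedded fixtures", {
  for (fx in c("table1", "table2")) {
    path <- system.file("extdata", paste0(fx, ".json"), package = "tautkin")
    expect_true(nzchar(path))
    expect_reaction_set_equal(read_reaction_set(path), load_fixture(fx))
  }
})
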