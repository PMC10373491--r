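test_that("variant names parse against the hotspot set with full checks", {
  hs <- demo_hotspots()
  v <- parse_variant_name("F85A_W57F_Y150F", hs)
  expect_s3_class(v, "variant")
  expect_equal(sum(v > 0), 3)
  expect_equal(variant_order(v, hs), 3L)

  ## wild-type sentinel and empty name are order-0
  expect_equal(variant_order(parse_variant_name("WT", hs), hs), 0L)
  expect_equal(variant_order(parse_variant_name("", hs), hs), 0L)

  ## primed-chain token forms all resolve to the same hotspot
  expect_equal(parse_variant_name("F85'A", hs), parse_variant_name("F85A", hs))

  ## assigning the wild-type letter parses but does not raise the order
  expect_equal(variant_order(parse_variant_name("F19F", hs), hs), 0L)

  expect_error(parse_variant_name("F99A", hs), "unknown hotspot")
  expect_error(parse_variant_name("A19G", hs), "wild-type mismatch")
  expect_error(parse_variant_name("F19", hs), "malformed")
  expect_error(parse_variant_name("F19A_F19C", hs), "duplicate substitution")
})

test_that("format/parse round-trips seeded random names", {
  hs <- demo_hotspots()
  lib <- sample_library(hs, l_max = 4, n = 100, seed = 7)
  for (nm in lib$variant_name) {
    expect_identical(format_variants(parse_variant_name(nm, hs), hs), nm)
  }
})

test_that("search space size follows the combinatorial formula", {
  expect_equal(search_space_size(4, 4, 20), 160000)
  expect_equal(search_space_size(8, 4, 20), 11200000)
  expect_equal(search_space_size(6, 6, 20), 6.4e7)
  expect_equal(search_space_size(8, 8, 20), 2.56e10)
  expect_equal(search_space_size(4, 4, 10), 1e4)
  expect_equal(search_space_size(1, 1, 1), 1)
  expect_error(search_space_size(4, 5, 20), "l_max")
})

test_that("search space size equals brute-force enumeration counts", {
  for (n_hot in 1:4) {
    for (l in seq_len(n_hot)) {
      for (aa in 1:4) {
        hs <- hotspot_set(position = seq_len(n_hot),
                          wt = rep("A", n_hot),
                          alphabet = c("A", "C", "D", "E")[seq_len(aa)])
        lib <- enumerate_library(hs, l)
        expect_equal(nrow(lib), search_space_size(n_hot, l, aa))
        expect_false(anyDuplicated(lib$variant_name) > 0)
      }
    }
  }
})

test_that("enumeration is deterministic, complete and streamable", {
  hs <- hotspot_set(position = 1:8, wt = rep("A", 8))
  lib1 <- enumerate_library(hs, 1)
  expect_equal(nrow(lib1), 160)  # 8 positions x 20 letters

  hs1 <- hotspot_set(position = 5L, wt = "A", alphabet = "A")
  expect_equal(nrow(enumerate_library(hs1, 1)), 1)

  ## slicing agrees with full enumeration
  hs2 <- tiny_hotspots()
  full <- enumerate_assignments(hs2, 2)
  slice <- enumerate_assignments(hs2, 2, indices = 5:11)
  expect_equal(slice, full[5:11, , drop = FALSE])
})

test_that("sampled libraries are distinct, reproducible and inside the space", {
  hs <- demo_hotspots()
  lib <- sample_library(hs, l_max = 4, n = 2000, seed = 3)
  expect_equal(nrow(lib), 2000)
  expect_false(anyDuplicated(lib$variant_name) > 0)
  lib2 <- sample_library(hs, l_max = 4, n = 2000, seed = 3)
  expect_identical(lib$variant_name, lib2$variant_name)

  ## every sampled variant parses and respects l_max
  a <- parse_variants(lib$variant_name[1:50], hs)
  expect_true(all(rowSums(a > 0) >= 1 & rowSums(a > 0) <= 4))

  ## n = full space returns the complete enumeration (as a set)
  hs_small <- hotspot_set(position = 1:2, wt = c("A", "A"),
                          alphabet = c("A", "C", "D"))
  full <- sample_library(hs_small, l_max = 2, n = 9, seed = 1)
  expect_setequal(full$variant_name, enumerate_library(hs_small, 2)$variant_name)

  expect_error(sample_library(hs_small, 2, 10, seed = 1), "exceeds")
})

test_that("hierarchical draws give a uniform mutant-order distribution", {
  hs <- hotspot_set(position = 1:8, wt = rep("A", 8))
  draws <- with_seed_local(11, gcnscreen:::draw_assignments(hs, 4, 10000))
  L <- rowSums(draws > 0)
  counts <- tabulate(L, nbins = 4)
  expected <- 10000 / 4
  sigma <- sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(counts - expected) < 3 * sigma))
})

test_that("dataset splits partition the indices at the requested sizes", {
  sp <- split_dataset(10000, c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(lengths(sp), c(train = 8000, validation = 1000, test = 1000))
  expect_setequal(unlist(sp), 1:10000)

  sp2 <- split_dataset(10, c(1, 0, 0), seed = 1)
  expect_equal(sort(sp2$train), 1:10)
  expect_length(sp2$validation, 0)

  for (seed in 1:5) {
    sp3 <- split_dataset(101, c(0.6, 0.25, 0.15), seed = seed)
    expect_setequal(unlist(sp3), 1:101)
    expect_equal(sum(lengths(sp3)), 101)
    expect_length(intersect(sp3$train, sp3$validation), 0)
    expect_length(intersect(sp3$train, sp3$test), 0)
    expect_length(intersect(sp3$validation, sp3$test), 0)
  }
  expect_error(split_dataset(10, c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("whitening gives zero mean, unit sd, and exact round-trips", {
  w <- whiten_labels(c(-10, -12, -14))
  expect_equal(mean(w$values), 0, tolerance = 1e-12)
  expect_equal(sd(w$values), 1, tolerance = 1e-12)

  y <- with_seed_local(5, rnorm(200, -11, 2.3))
  w2 <- whiten_labels(y)
  expect_equal(mean(w2$values), 0, tolerance = 1e-9)
  expect_equal(sd(w2$values), 1, tolerance = 1e-9)
  expect_equal(unwhiten_labels(w2$values, w2$params), y, tolerance = 1e-9)

  ## idempotence: whitening an already-whitened vector changes nothing
  w3 <- whiten_labels(w2$values)
  expect_equal(w3$values, w2$values, tolerance = 1e-9)

  expect_error(whiten_labels(rep(3, 5)), "constant")
})

test_that("coverage percentages match the printed display convention", {
  expect_equal(coverage_percent(10000, 160000), 6.25)
  expect_equal(coverage_percent(10000, 2.56e10), 3.90625e-05)
  expect_equal(coverage_percent(7, 7), 100)
  expect_identical(format_coverage(coverage_percent(10000, 160000)), "6.25")
  expect_identical(format_coverage(coverage_percent(10000, 6.4e7)), "0.015")
  expect_identical(format_coverage(coverage_percent(10000, 2.56e10)), "0.000039")
  expect_identical(format_coverage(coverage_percent(50000, 2.56e10)), "0.00019")
})

test_that("library files round-trip through TSV with header checks", {
  lib <- tibble::tibble(variant_name = c("WT", "F19A", "F19A_W57C"),
                        energy = c(-10, -11.5, -9.25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_library(lib, path)
  back <- read_library(path)
  expect_equal(back$variant_name, lib$variant_name)
  expect_equal(back$energy, lib$energy)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tenergy", "WT\t-10"), bad)
  expect_error(read_library(bad), "variant_name")
})

test_that("variant sequences apply substitutions to the reference", {
  hs <- hotspot_set(position = c(3L, 7L), wt = c("A", "C"), chain = "",
                    alphabet = c("A", "C", "D", "E"),
                    reference_sequence = "GGATTACAGG")
  seqs <- variant_sequences(c("WT", "A3D", "A3D_C7E"), hs)
  expect_identical(unname(seqs), c("GGATTACAGG", "GGDTTACAGG", "GGDTTAEAGG"))

  path <- withr::local_tempfile(fileext = ".fasta")
  write_variant_fasta(seqs, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, ">")), 3)

  bad <- hotspot_set(position = 3L, wt = "T", alphabet = c("A", "T"))
  expect_error(variant_sequences("WT", bad, reference = "GGATTACAGG"),
               "disagrees")
})

test_that("hotspot configs round-trip through JSON", {
  hs <- demo_hotspots(alphabet = c("A", "C", "D"))
  path <- withr::local_tempfile(fileext = ".json")
  write_hotspots(hs, path)
  back <- read_hotspots(path)
  expect_equal(back$positions, hs$positions)
  expect_equal(back$alphabet, hs$alphabet)

  bundled <- read_hotspots(system.file("extdata", "hotspots_d1.json",
                                       package = "gcnscreen"))
  expect_equal(bundled$positions$label, c("F19", "W57", "Y150", "F85'"))
  expect_length(bundled$alphabet, 20)
})
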