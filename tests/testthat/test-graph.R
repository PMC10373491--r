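test_that("property tables load standardized, with imputation and errors", {
  tbl <- load_property_table()
  expect_s3_class(tbl, "aaindex_table")
  expect_equal(dim(tbl$values), c(20, 20))
  expect_true(all(abs(colMeans(tbl$values)) < 1e-9))
  expect_true(all(abs(apply(tbl$values, 2, sd) - 1) < 1e-9))

  sub <- load_property_table(ids = c("KYTJ820101", "GRAR740103"))
  expect_equal(sub$ids, c("KYTJ820101", "GRAR740103"))
  expect_error(load_property_table(ids = "NOPE123456"), "NOPE123456")

  ## TSV dialect with a missing value: imputed with the property mean
  path <- withr::local_tempfile(fileext = ".tsv")
  vals <- setNames(as.list(c(NA, 2:20)), AA_ALPHABET)
  writeLines(paste(c("id", AA_ALPHABET), collapse = "\t"), path)
  cat("TEST01\t", paste(c("NA", 2:20), collapse = "\t"), "\n",
      sep = "", file = path, append = TRUE)
  t2 <- load_property_table(path)
  expect_equal(unname(colnames(t2$values)), "TEST01")
  expect_false(anyNA(t2$values))
})

test_that("node featurization tracks variant substitutions row-wise", {
  ctx <- demo_context()
  X0 <- featurize_nodes(ctx$selection, ctx$table)
  expect_equal(dim(X0), c(23, 20))
  ## wild-type rows equal the property vectors of the wild-type letters
  expect_equal(unname(X0[1, ]),
               unname(ctx$table$values["F", ]))  # F19 is node 1

  ## single mutant differs from wild type in exactly one row
  X1 <- featurize_nodes(ctx$selection, ctx$table, "F85A", ctx$hotspots)
  diff_rows <- unname(which(rowSums(abs(X1 - X0)) > 0))
  node_85 <- hotspot_node_index(ctx$hotspots, ctx$selection)[4]
  expect_equal(diff_rows, node_85)
  expect_equal(unname(X1[node_85, ]), unname(ctx$table$values["A", ]))

  ## residues sharing an amino acid share a feature row
  labs <- ctx$selection$residues$wt
  same <- which(labs == "A")
  expect_equal(X0[same[1], ], X0[same[2], ], ignore_attr = TRUE)

  ## substitution outside the selection errors
  hs_bad <- hotspot_set(999L, "F")
  expect_error(featurize_nodes(ctx$selection, ctx$table, "F999A", hs_bad),
               "absent")
})

test_that("edge weights are inverse distances, symmetric, zero-diagonal", {
  sel2 <- residue_selection(1:2, "", c("A", "C"),
                            rbind(c(0, 0, 0), c(2, 0, 0)))
  E <- edge_weights(sel2)
  expect_equal(E, rbind(c(0, 0.5), c(0.5, 0)))

  ## collinear unit-spaced points: off-diagonals 1, 1, 1/2
  sel3 <- residue_selection(1:3, "", c("A", "C", "D"),
                            cbind(0:2, 0, 0))
  E3 <- edge_weights(sel3)
  expect_equal(E3[1, 2], 1); expect_equal(E3[2, 3], 1)
  expect_equal(E3[1, 3], 0.5)

  sel <- tiny_selection(23)
  E23 <- edge_weights(sel)
  expect_equal(E23, t(E23))
  expect_true(all(diag(E23) == 0))

  dup <- residue_selection(1:2, "", c("A", "A"),
                           rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_error(edge_weights(dup), "coincident")
})

test_that("adjacency normalization is symmetric with spectrum in [-1, 1]", {
  ## complete unweighted 3-node graph: off-diagonals 1/2
  W <- matrix(1, 3, 3) - diag(3)
  An <- normalize_adjacency(W)
  expect_equal(An, rbind(c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0)))

  expect_equal(normalize_adjacency(diag(4)), diag(4))

  for (seed in 1:5) {
    W <- random_weights(10, seed)
    An <- normalize_adjacency(W)
    expect_equal(An, t(An), tolerance = 1e-12)
    ev <- eigen(An, symmetric = TRUE, only.values = TRUE)$values
    expect_true(max(abs(ev)) <= 1 + 1e-9)
  }

  W0 <- rbind(c(0, 0), c(0, 1))
  expect_error(normalize_adjacency(W0), "isolated")
})

test_that("graph assembly is pure, edge-invariant across variants", {
  ctx <- demo_context()
  g_wt <- build_graph(ctx$selection, ctx$table)
  g_mut <- build_graph(ctx$selection, ctx$table, "F85A_W57F", ctx$hotspots)
  expect_identical(g_wt$E, g_mut$E)
  expect_identical(g_wt$A_norm, g_mut$A_norm)
  expect_equal(dim(g_wt$X), c(23, 20))
  expect_equal(dim(g_wt$E), c(23, 23))

  ## ones mode: normalized complete graph, independent of coordinates
  g1 <- build_graph(ctx$selection, ctx$table, edge_mode = "ones")
  sel_other <- tiny_selection(23)
  g2 <- build_graph(sel_other, ctx$table, edge_mode = "ones")
  expect_equal(g1$A_norm, g2$A_norm)
  expect_equal(unique(round(g1$A_norm[1, -1], 12)), 1 / 22)

  ## purity: identical inputs give identical outputs
  g_wt2 <- build_graph(ctx$selection, ctx$table)
  expect_identical(g_wt$X, g_wt2$X)
  expect_identical(g_wt$A_norm, g_wt2$A_norm)
})

test_that("graph construction is equivariant to node permutation", {
  ctx <- demo_context()
  perm <- with_seed_local(9, sample(23))
  sel_p <- residue_selection(
    ctx$selection$residues$position[perm],
    ctx$selection$residues$chain[perm],
    ctx$selection$residues$wt[perm],
    ctx$selection$coords[perm, , drop = FALSE]
  )
  g <- build_graph(ctx$selection, ctx$table, "F85A", ctx$hotspots)
  gp <- build_graph(sel_p, ctx$table, "F85A", ctx$hotspots)
  expect_equal(gp$X, g$X[perm, , drop = FALSE], ignore_attr = TRUE)
  expect_equal(gp$E, g$E[perm, perm])
  expect_equal(gp$A_norm, g$A_norm[perm, perm])
})

test_that("PDB-format coordinates can back a residue selection", {
  skip_if_not_installed("bio3d")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  atoms <- c(
    "ATOM      1  N   PHE A  19      11.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  PHE A  19      12.000   2.500   3.500  1.00  0.00           C",
    "ATOM      3  CA  TRP A  57       1.000   5.000   9.000  1.00  0.00           C",
    "ATOM      4  CA  TYR A 150       4.000   8.000   2.000  1.00  0.00           C",
    "END")
  writeLines(atoms, pdb)
  sel <- read_selection_pdb(pdb, position = c(19, 57, 150), chain = "A")
  expect_equal(sel$residues$wt, c("F", "W", "Y"))
  expect_equal(unname(sel$coords[1, ]), c(12, 2.5, 3.5))
  expect_error(read_selection_pdb(pdb, position = 99, chain = "A"), "99")
})
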