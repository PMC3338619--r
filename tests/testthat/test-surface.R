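test_that("SASA of a lone atom matches the analytic sphere area", {
  one <- structure_model(data.frame(resno = 1L, resid = "GLY",
                                    elety = "CA", element = "C",
                                    x = 0, y = 0, z = 0))
  sm <- compute_sasa(one, probe_radius = 1.4, n_sphere_points = 500)
  analytic <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(unname(sm$sasa["1"]), analytic, tolerance = 1e-9)
  expect_gte(unname(sm$rel_sasa["1"]), 0.95)
})

test_that("two identical distant residues have equal SASA by symmetry", {
  at <- rbind(data.frame(resno = 1L, resid = "ALA", elety = c("CA", "CB"),
                         element = "C", x = c(0, 1.5), y = 0, z = 0),
              data.frame(resno = 2L, resid = "ALA", elety = c("CA", "CB"),
                         element = "C", x = c(100, 101.5), y = 0, z = 0))
  sm <- compute_sasa(structure_model(at))
  expect_equal(unname(sm$sasa["1"]), unname(sm$sasa["2"]), tolerance = 1e-9)
})

test_that("SASA is converged: doubling the mesh changes areas < 2%", {
  fx <- gen_structure_fixture(40, seed = 3)
  s1 <- compute_sasa(fx$structure, n_sphere_points = 240)
  s2 <- compute_sasa(fx$structure, n_sphere_points = 480)
  # total surface and the typical exposed residue converge below 2%;
  # near-buried residues have tiny areas where relative error is moot
  expect_lt(abs(sum(s1$sasa) - sum(s2$sasa)) / sum(s2$sasa), 0.02)
  expo <- s2$rel_sasa > 0.15
  rel <- abs(s1$sasa[expo] - s2$sasa[expo]) / s2$sasa[expo]
  expect_lt(median(rel), 0.02)
  # burial/exposure calls are unchanged by mesh refinement
  expect_identical(s1$rel_sasa < 0.15, s2$rel_sasa < 0.15)
})

test_that("designed buried core and exposed cluster are recovered for any seed", {
  for (s in c(1, 17, 123)) {
    fx <- gen_structure_fixture(60, seed = s)
    sm <- compute_sasa(fx$structure)
    expect_true(all(sm$rel_sasa[as.character(fx$buried)] < 0.15))
    expect_true(all(sm$rel_sasa[as.character(fx$top_face)] >= 0.15))
    bs <- surface_patches(fx$top_face, sm, neighbor_cutoff = 8,
                          min_patch_size = 6)
    expect_length(bs$patches, 1L)
    expect_setequal(bs$patches[[1]], fx$top_face)
    expect_equal(bs$accepted, 1L)
  }
})

test_that("discrimination separates buried, isolated and candidates", {
  fx <- gen_structure_fixture(60, seed = 5)
  sm <- compute_sasa(fx$structure)
  # significant set: the buried core, the top face, and nothing else
  sig <- c(fx$buried, fx$top_face)
  disc <- discriminate_residues(sig, sm)
  expect_setequal(disc$buried, fx$buried)
  expect_setequal(disc$candidates, fx$top_face)
  expect_length(disc$isolated, 0)

  # two lone significant surface residues far apart are both isolated
  corners <- sm$residues[c(1, length(sm$residues))]
  d <- dist(cspkd:::residue_coords(sm, corners))
  expect_gt(as.numeric(d), 8)  # fixture geometry guarantees separation
  disc2 <- discriminate_residues(corners, sm)
  expect_setequal(disc2$isolated, corners)

  # empty significant set: empty result, no error
  disc3 <- discriminate_residues(integer(0), sm)
  expect_length(disc3$candidates, 0)

  expect_error(discriminate_residues(9999L, sm), "absent.*9999")
})

test_that("published 3P-peptide accounting: 73 significant -> 59 surface", {
  ref <- pebp1_reference_sets()$raf1_3p
  # significant set: the printed buried and isolated residues plus
  # enough pocket-region ids to reach the printed total
  n_other <- ref$n_total - length(ref$buried) - length(ref$isolated)
  others <- setdiff(60:187, c(ref$buried, ref$isolated))[seq_len(n_other)]
  disc <- apply_discrimination(c(ref$buried, ref$isolated, others),
                               buried = ref$buried,
                               isolated = ref$isolated)
  expect_length(disc$candidates, ref$n_surface)
  expect_equal(length(disc$candidates), 59L)
})

test_that("patches equal brute-force connected components and partition candidates", {
  set.seed(21)
  for (rep in 1:5) {
    fx <- gen_structure_fixture(sample(27:64, 1), seed = rep)
    sm <- fx$structure
    cand <- sort(sample(sm$residues, min(25, length(sm$residues))))
    bs <- surface_patches(cand, sm, neighbor_cutoff = 6, min_patch_size = 3)
    # partition
    expect_setequal(unlist(bs$patches), cand)
    expect_equal(sum(lengths(bs$patches)), length(cand))
    # oracle agreement
    ora <- components_oracle(cand, cspkd:::residue_coords(sm, cand), 6)
    expect_equal(length(bs$patches), length(ora))
    key <- function(ps) sort(vapply(ps, function(p)
      paste(sort(p), collapse = ","), character(1)))
    expect_equal(key(bs$patches), key(ora))
  }
})

test_that("raising the cutoff never increases the number of patches", {
  fx <- gen_structure_fixture(50, seed = 9)
  set.seed(33)
  cand <- sort(sample(fx$structure$residues, 20))
  n_prev <- Inf
  for (cutoff in c(4, 6, 8, 12, 20, 60)) {
    bs <- surface_patches(cand, fx$structure, neighbor_cutoff = cutoff,
                          min_patch_size = 1)
    expect_lte(length(bs$patches), n_prev)
    n_prev <- length(bs$patches)
  }
})

test_that("small patches are reported but rejected", {
  fx <- gen_structure_fixture(64, seed = 2)
  sm <- fx$structure
  # a singleton candidate forms one rejected patch
  bs <- surface_patches(fx$top_face[1], sm, min_patch_size = 6)
  expect_length(bs$patches, 1L)
  expect_length(bs$accepted, 0L)
  expect_equal(unname(bs$labels), "small_patch")
  # all candidates mutually within cutoff collapse to one accepted patch
  bs2 <- surface_patches(fx$top_face, sm, neighbor_cutoff = 1000,
                         min_patch_size = 6)
  expect_length(bs2$patches, 1L)
  expect_setequal(bs2$patches[[1]], fx$top_face)
})

test_that("end-to-end mapping labels every significant residue exactly once", {
  fx <- gen_structure_fixture(60, seed = 4)
  sm <- compute_sasa(fx$structure)
  classes <- setNames(rep("fast", length(c(fx$buried, fx$top_face))),
                      c(fx$buried, fx$top_face))
  bs <- map_binding_surface(classes, sm)
  expect_setequal(names(bs$labels), as.character(c(fx$buried, fx$top_face)))
  expect_true(all(bs$labels[as.character(fx$buried)] == "buried"))
  expect_true(all(bs$labels[as.character(fx$top_face)] == "fast"))

  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_surface_report(bs, p1, p2)
  ann <- read.delim(p1, comment.char = "#")
  expect_equal(nrow(ann), length(bs$labels))
})

test_that("structure reading round-trips the generated PDB fixture", {
  path <- withr::local_tempfile(fileext = ".pdb")
  fx <- gen_structure_fixture(30, seed = 6, path = path)
  sm <- read_structure(path)
  expect_equal(sm$residues, fx$structure$residues)
  expect_equal(nrow(sm$atoms), nrow(fx$structure$atoms))
  expect_equal(sm$atoms$x, fx$structure$atoms$x, tolerance = 1e-3)
})
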