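frag_path <- function() {
  system.file("extdata", "shp2_fragment_synthetic.pdb", package = "shp2dms")
}

test_that("PDB reading preserves frames, order and altloc rule", {
  frames <- synthetic_shp2_fragment()
  single <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(frames[1], single)
  expect_length(read_structure(single), 1L)

  five <- withr::local_tempfile(fileext = ".pdb")
  shifted <- lapply(1:5, function(i) transform_frame(frames[[1]],
                                                     shift = c(i, 0, 0)))
  write_test_pdb(shifted, five)
  fr5 <- read_structure(five)
  expect_length(fr5, 5L)
  expect_equal(fr5[[3]]$x - fr5[[1]]$x, rep(2, nrow(fr5[[1]])))

  ## highest-occupancy altloc wins
  alt <- data.frame(chain = "A", resno = 1L, resid = "GLY",
                    elety = c("CA", "CA"), x = c(0, 9), y = 0, z = 0,
                    occ = c(0.4, 0.6), altloc = c("A", "B"),
                    stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(list(alt), p)
  fr <- read_structure(p)
  expect_equal(nrow(fr[[1]]), 1L)
  expect_equal(fr[[1]]$x, 9)
})

test_that("distances are Euclidean and min-pair takes the set minimum", {
  fr <- data.frame(chain = "A", resno = c(1, 1, 2, 2, 2), insert = "",
                   resid = "GLY", elety = c("A1", "A2", "B1", "B2", "B3"),
                   x = c(0, 1, 3, 5, 2), y = c(0, 1, 4, 0, 2),
                   z = c(0, 0, 0, 0, 1), stringsAsFactors = FALSE)
  self <- atom_distance(fr, list(resno = 1, elety = "A1"),
                        list(resno = 1, elety = "A1"))
  expect_equal(self, 0)
  expect_equal(atom_distance(fr, list(resno = 1, elety = "A1"),
                             list(resno = 2, elety = "B1")), 5)  # 3-4-5
  ## 2x3 min-pair vs exhaustive enumeration
  mp <- min_pair_distance(fr, list(resno = 1, elety = c("A1", "A2")),
                          list(resno = 2, elety = c("B1", "B2", "B3")))
  pts <- as.matrix(fr[c("x", "y", "z")])
  oracle <- min(apply(expand.grid(1:2, 3:5), 1,
                      function(ij) sqrt(sum((pts[ij[1], ] - pts[ij[2], ])^2))))
  expect_equal(mp, oracle)
  ## bound: min over sets never exceeds any individual pair
  expect_lte(mp, atom_distance(fr, list(resno = 1, elety = "A1"),
                               list(resno = 2, elety = "B2")))
  expect_error(atom_distance(fr, list(resno = 9, elety = "A1"),
                             list(resno = 1, elety = "A1")),
               "no atom matches")
})

test_that("dihedrals handle cis, trans and collinear degeneracy", {
  mk <- function(coords) {
    data.frame(chain = "A", resno = 1:4, insert = "", resid = "GLY",
               elety = c("P1", "P2", "P3", "P4"),
               x = coords[, 1], y = coords[, 2], z = coords[, 3],
               stringsAsFactors = FALSE)
  }
  sel <- lapply(1:4, function(i) list(resno = i, elety = paste0("P", i)))
  cis <- mk(rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(do.call(dihedral, c(list(cis), sel)), 0)
  trans <- mk(rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)))
  expect_equal(do.call(dihedral, c(list(trans), sel)), 180)
  line <- mk(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)))
  expect_error(do.call(dihedral, c(list(line), sel)), "collinear")
})

test_that("geometry agrees with brute-force oracles on random frames", {
  set.seed(41)
  for (i in 1:100) {
    fr <- random_frame(8)
    pts <- as.matrix(fr[c("x", "y", "z")])
    sel <- function(i) list(resno = i, elety = "X")
    d <- atom_distance(fr, sel(1), sel(2))
    expect_equal(d, sqrt(sum((pts[1, ] - pts[2, ])^2)), tolerance = 1e-9)
    ang <- dihedral(fr, sel(1), sel(2), sel(3), sel(4))
    oracle <- dihedral_oracle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_equal(ang, oracle, tolerance = 1e-6)
    ## triangle inequality across any three atoms
    d12 <- atom_distance(fr, sel(1), sel(2))
    d23 <- atom_distance(fr, sel(2), sel(3))
    d13 <- atom_distance(fr, sel(1), sel(3))
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("metrics are rigid-motion invariant; reflection flips dihedrals", {
  set.seed(42)
  for (i in 1:25) {
    fr <- random_frame(6)
    rot <- random_rotation()
    moved <- transform_frame(fr, rot, shift = stats::rnorm(3, sd = 10))
    sel <- function(i) list(resno = i, elety = "X")
    expect_equal(atom_distance(moved, sel(1), sel(2)),
                 atom_distance(fr, sel(1), sel(2)), tolerance = 1e-9)
    expect_equal(min_pair_distance(moved, list(resno = 1:3, elety = "X"),
                                   list(resno = 4:6, elety = "X")),
                 min_pair_distance(fr, list(resno = 1:3, elety = "X"),
                                   list(resno = 4:6, elety = "X")),
                 tolerance = 1e-9)
    expect_equal(dihedral(moved, sel(1), sel(2), sel(3), sel(4)),
                 dihedral(fr, sel(1), sel(2), sel(3), sel(4)),
                 tolerance = 1e-6)
    mirror <- fr
    mirror$z <- -mirror$z
    expect_equal(dihedral(mirror, sel(1), sel(2), sel(3), sel(4)),
                 -dihedral(fr, sel(1), sel(2), sel(3), sel(4)),
                 tolerance = 1e-6)
  }
})

test_that("psi and chi1 match bio3d torsions on the packaged fragment", {
  fr <- read_structure(frag_path())[[1]]
  pdb <- bio3d::read.pdb(frag_path(), verbose = FALSE)
  tor <- bio3d::torsion.pdb(pdb)
  lab <- rownames(tor$tbl)
  ang_diff <- function(a, b) min(abs(a - b), 360 - abs(a - b))
  psi_ours <- psi_angle(fr, 218)
  psi_bio3d <- tor$tbl[grepl("^218\\.", lab), "psi"]
  expect_lt(ang_diff(psi_ours, psi_bio3d), 1e-3)
  chi1_ours <- chi1_angle(fr, 469)
  chi1_bio3d <- tor$tbl[grepl("^469\\.", lab), "chi1"]
  expect_lt(ang_diff(chi1_ours, chi1_bio3d), 1e-3)
})

test_that("the built-in metric set reproduces per-atom oracle values", {
  frames <- read_structure(frag_path())
  expect_length(frames, 2L)
  ts <- metric_timeseries(frames, shp2_metric_specs())
  expect_equal(nrow(ts), 2L * 7L)
  fr <- frames[[1]]
  pt <- function(resno, elety) {
    unlist(fr[fr$resno == resno & fr$elety == elety, c("x", "y", "z")])
  }
  ## salt bridge: exhaustive min over the 2 x 4 nitrogen/oxygen pairs
  ns <- rbind(pt(111, "NH1"), pt(111, "NH2"))
  os <- rbind(pt(249, "OE1"), pt(249, "OE2"), pt(250, "OE1"), pt(250, "OE2"))
  oracle_sb <- min(apply(expand.grid(1:2, 1:4), 1, function(ij) {
    sqrt(sum((ns[ij[1], ] - os[ij[2], ])^2))
  }))
  got <- function(m, f) ts$value[ts$metric == m & ts$frame == f]
  expect_equal(got("r111_e249_250_saltbridge", 1), oracle_sb,
               tolerance = 1e-9)
  expect_equal(got("wpd_d425_c459_ca", 1),
               sqrt(sum((pt(425, "CA") - pt(459, "CA"))^2)), tolerance = 1e-9)
  expect_equal(got("t218_psi", 1),
               dihedral_oracle(pt(218, "N"), pt(218, "CA"), pt(218, "C"),
                               pt(219, "N")), tolerance = 1e-6)
  expect_equal(got("f469_chi1", 1),
               dihedral_oracle(pt(469, "N"), pt(469, "CA"), pt(469, "CB"),
                               pt(469, "CG")), tolerance = 1e-6)
  ## the two frames toggle the planted conformational states
  state <- function(m, f) ts$state[ts$metric == m & ts$frame == f]
  expect_equal(state("r111_e249_250_saltbridge", 1), "formed")
  expect_equal(state("r111_e249_250_saltbridge", 2), "broken")
  expect_equal(state("wpd_d425_c459_ca", 1), "open")
  expect_equal(state("wpd_d425_c459_ca", 2), "closed")
})

test_that("metric specs failing after frame 1 flag rows and continue", {
  frames <- synthetic_shp2_fragment()
  ## drop an atom from frame 2 only
  frames[[2]] <- frames[[2]][!(frames[[2]]$resno == 459 &
                                 frames[[2]]$elety == "CA"), ]
  specs <- shp2_metric_specs()[c("wpd_d425_c459_ca", "h114_t218_ca")]
  ts <- metric_timeseries(frames, specs)
  expect_equal(nrow(ts), 4L)
  expect_true(is.na(ts$value[ts$frame == 2 & ts$metric == "wpd_d425_c459_ca"]))
  expect_false(anyNA(ts$value[ts$metric == "h114_t218_ca"]))
  ## a spec that cannot resolve in frame 1 is a hard error
  bad <- list(nope = list(kind = "atom_distance",
                          a = list(resno = 999, elety = "CA"),
                          b = list(resno = 459, elety = "CA")))
  expect_error(metric_timeseries(frames, bad), "no atom matches")
})
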