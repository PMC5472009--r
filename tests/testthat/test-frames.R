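test_that("grid sampling spans the bounding box with ceil(extent/spacing)", {
  corners <- fakeStructure(data.frame(name = c("CA", "CA"), resid = "GLY",
                                      resno = 1:2, x = c(0, 25),
                                      y = c(0, 25), z = c(0, 25)))
  pts <- sampleGrid(corners, spacing = 10)
  expect_equal(nrow(pts), 64)                    # 4 points per axis
  expect_setequal(unique(pts[, 1]), c(0, 10, 20, 30))
  # degenerate single-atom structure: exactly one point at the atom
  single <- fakeStructure(data.frame(name = "CA", resid = "GLY", resno = 1,
                                     x = 3, y = 4, z = 5))
  expect_equal(sampleGrid(single, 10), matrix(c(3, 4, 5), 1))
  # a coarser grid is strictly sparser
  expect_lt(nrow(sampleGrid(corners, 25)), nrow(pts))
  expect_error(sampleGrid(corners, 0), "spacing")
})

test_that("center residue is the owner of the nearest eligible atom", {
  s <- syntheticStructure(30, seed = 5, noise = 0.05)
  rt <- residueTable(s)
  ca7 <- s@atoms[s@atoms$resno == 7 & s@atoms$name == "CA", ]
  expect_equal(pickCenterResidue(s, c(ca7$x, ca7$y, ca7$z)), rt$key[7])
})

test_that("equidistant ties go to the lowest atom serial", {
  s <- fakeStructure(data.frame(
    name = rep(c("N", "CA", "C"), 2), resid = "GLY", resno = c(3, 3, 3, 9, 9, 9),
    x = c(-3, -2, -1, 1, 2, 3), y = 0, z = 0))
  # point at origin is exactly 1 from atom serial 3 (res 3) and serial 4 (res 9)
  expect_equal(pickCenterResidue(s, c(0, 0, 0)), "A:3:.")
})

test_that("center picks agree with a brute-force all-atom scan", {
  s <- syntheticStructure(30, seed = 6, noise = 0.05)
  a <- s@atoms
  set.seed(42)
  for (r in 1:25) {
    p <- runif(3, min = c(min(a$x), min(a$y), min(a$z)),
               max = c(max(a$x), max(a$y), max(a$z)))
    d2 <- (a$x - p[1])^2 + (a$y - p[2])^2 + (a$z - p[3])^2
    i <- which.min(d2)
    expect_equal(pickCenterResidue(s, p),
                 paste("A", a$resno[i], ".", sep = ":"))
  }
})

test_that("the backbone frame follows the stated axis conventions", {
  s <- axisResidue()
  fr <- buildFrame(s, "A:1:.")
  expect_equal(fr@axes["x", ], c(1, 0, 0))
  expect_equal(fr@axes["z", ], c(0, 0, 1))
  expect_equal(fr@axes["y", ], c(0, 1, 0))
  expect_equal(fr@origin, c(0, 0, 1))
  # mirrored CB flips z (and hence y)
  mir <- axisResidue()
  mir@atoms$z[mir@atoms$name == "CB"] <- -1
  fr2 <- buildFrame(mir, "A:1:.")
  expect_equal(fr2@axes["z", ], c(0, 0, -1))
  expect_equal(fr2@axes["y", ], c(0, -1, 0))
})

test_that("collinear backbones raise a degenerate-frame error", {
  s <- fakeStructure(data.frame(name = c("N", "CA", "C"), resid = "GLY",
                                resno = 1, x = c(0, 1, 2), y = 0, z = 0))
  expect_error(buildFrame(s, "A:1:."), "degenerate|collinear")
})

test_that("frames are orthonormal, right-handed and equivariant", {
  s <- syntheticStructure(40, seed = 8, noise = 0.08)
  rt <- residueTable(s)
  frames <- lapply(rt$key, function(k) buildFrame(s, k))
  for (fr in frames) {
    A <- fr@axes
    expect_lt(max(abs(A %*% t(A) - diag(3))), 1e-8)
    expect_lt(max(abs(crossprod3(A["x", ], A["y", ]) - A["z", ])), 1e-8)
  }
  for (seed in 1:5) {
    mo <- randomRigidMotion(seed)
    s2 <- transformStructure(s, mo)
    for (j in c(1, 17, 40)) {
      fr0 <- frames[[j]]
      fr1 <- buildFrame(s2, rt$key[j])
      expect_lt(max(abs(fr1@axes - fr0@axes %*% t(mo$R))), 1e-6)
      expect_lt(max(abs(fr1@origin - (drop(mo$R %*% fr0@origin) + mo$t))),
                1e-6)
    }
  }
})

test_that("boxes strip the center side chain but keep neighbors and backbone", {
  neighbor <- data.frame(name = c("N", "CA", "C", "CD1"), resid = "LEU",
                         resno = 2, x = c(4, 5, 6, 3), y = c(0, 1, 0, 3),
                         z = c(0, 0, 0, 3))
  s <- axisResidue(extra = neighbor)
  box <- extractBox(s, "A:1:.")
  # center residue: backbone kept, CB (the side chain here) removed
  expect_true(all(c(1, 2, 3, 4) %in% box@atoms$serial))   # N CA C O
  expect_false(5 %in% box@atoms$serial)                   # own CB
  expect_true(9 %in% box@atoms$serial)                    # neighbor's CD1
  expect_equal(box@label, "A")
})

test_that("the box cube is half-open", {
  far <- data.frame(name = c("N", "N"), resid = "GLY", resno = 3:4,
                    x = c(10, -10), y = 0.0, z = 1.0)
  # local coords relative to origin (0,0,1) with identity axes:
  # (10, 0, 0) excluded, (-10, 0, 0) included
  s <- axisResidue(extra = far)
  box <- extractBox(s, "A:1:.")
  expect_false(6 %in% box@atoms$serial)
  expect_true(7 %in% box@atoms$serial)
  loc <- box@atoms[box@atoms$serial == 7, c("x", "y", "z")]
  expect_equal(as.numeric(loc), c(-10, 0, 0))
})

test_that("box contents are invariant under global rigid motions", {
  s <- syntheticStructure(30, seed = 9, noise = 0.05)
  key <- residueTable(s)$key[12]
  box0 <- extractBox(s, key)
  for (seed in 3:6) {
    box1 <- extractBox(transformStructure(s, randomRigidMotion(seed)), key)
    expect_equal(box1@atoms$serial, box0@atoms$serial)
    expect_lt(max(abs(as.matrix(box1@atoms[, c("x", "y", "z")]) -
                      as.matrix(box0@atoms[, c("x", "y", "z")]))), 1e-6)
  }
})
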