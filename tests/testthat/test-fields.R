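test_that("grid construction follows the floor(extent/spacing)+1 rule", {
  single <- aligned_molecule("A", data.frame(
    element = "C", x = 0, y = 0, z = 0, charge = 0, steric = 1,
    hydrophobicity = 0, hbd = 0, hba = 0))
  g <- build_grid(list(single), field_config(spacing = 2, margin = 4))
  expect_equal(g$shape, c(5L, 5L, 5L))
  expect_equal(g$origin, c(-4, -4, -4))
  pts <- grid_points(g)
  expect_equal(colMeans(pts), c(0, 0, 0))  # centered on the atom

  g0 <- build_grid(list(single), field_config(spacing = 2, margin = 0))
  expect_equal(g0$shape, c(1L, 1L, 1L))
  expect_error(build_grid(list(), field_config()), class = "duotox_config_error")
})

test_that("grid covers every atom of a multi-molecule set within the margin", {
  w <- small_world()
  cfg <- field_config()
  g <- build_grid(w$mols, cfg)
  xyz <- do.call(rbind, lapply(w$mols, duotox:::coords_matrix))
  lo <- g$origin; hi <- g$origin + (g$shape - 1) * g$spacing
  expect_true(all(t(xyz) >= lo - 1e-9))
  # upper face may fall short of max+margin by < spacing (floor rule) but
  # never cuts an atom
  expect_true(all(t(xyz) <= hi + g$spacing + 1e-9))
})

test_that("similarity index matches its closed form and brute-force oracle", {
  one <- aligned_molecule("A", data.frame(
    element = "C", x = 0, y = 0, z = 0, charge = 1, steric = 1,
    hydrophobicity = 1, hbd = 1, hba = 1))
  cfg <- field_config(attenuation_alpha = 0.3)
  expect_equal(similarity_index(one, c(0, 0, 0), "S", cfg), -1)
  expect_equal(similarity_index(one, c(10, 0, 0), "S", cfg), -exp(-30))

  toy <- toy_molecule()
  pt <- c(0.5, 1.0, -0.3)
  for (f in c("S", "E", "H", "D", "A")) {
    w <- switch(f, S = toy$atoms$steric, E = toy$atoms$charge,
                H = toy$atoms$hydrophobicity, D = toy$atoms$hbd,
                A = toy$atoms$hba)
    # independent per-atom summation oracle
    expected <- 0
    for (i in 1:3) {
      r2 <- sum((c(toy$atoms$x[i], toy$atoms$y[i], toy$atoms$z[i]) - pt)^2)
      expected <- expected - w[i] * exp(-0.3 * r2)
    }
    expect_equal(similarity_index(toy, pt, f, cfg), expected, tolerance = 1e-12)
  }
})

test_that("attenuation is monotone and sign convention holds", {
  one <- aligned_molecule("A", data.frame(
    element = "C", x = 0, y = 0, z = 0, charge = -0.4, steric = 1.3,
    hydrophobicity = 0.7, hbd = 1, hba = 0))
  cfg <- field_config()
  r <- seq(0, 8, by = 0.25)
  for (f in c("S", "H", "D")) {  # non-negative weights -> non-positive index
    v <- similarity_index(one, cbind(r, 0, 0), f, cfg)
    expect_true(all(v <= 0))
    expect_true(all(diff(abs(v)) <= 1e-12))
  }
})

test_that("similarity index is equivariant under rigid motions", {
  toy <- toy_molecule()
  cfg <- field_config()
  pts <- matrix(rnorm(30), 10, 3)
  set.seed(31)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- 0.8
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  shift <- c(3, -2, 1)
  moved <- toy
  xyz <- duotox:::coords_matrix(toy) %*% t(R)
  moved$atoms$x <- xyz[, 1] + shift[1]
  moved$atoms$y <- xyz[, 2] + shift[2]
  moved$atoms$z <- xyz[, 3] + shift[3]
  pts_moved <- sweep(pts %*% t(R), 2, shift, "+")
  for (f in c("S", "E", "H")) {
    expect_equal(similarity_index(moved, pts_moved, f, cfg),
                 similarity_index(toy, pts, f, cfg), tolerance = 1e-9)
  }
})

test_that("descriptor assembly: identity rows, filtering, block scaling", {
  toy <- toy_molecule("T1"); toy2 <- toy_molecule("T2")
  cfg <- field_config(column_drop_sigma = 0, block_scaling = "none")
  d <- assemble_descriptors(list(toy, toy2), cfg)
  expect_equal(d$X[1, ], d$X[2, ])  # identical molecules -> identical rows
  expect_equal(ncol(d$X), 5 * prod(d$grid$shape))  # sigma 0 drops nothing

  w <- small_world()
  # descriptors equal direct pointwise evaluation at every kept column
  d2 <- assemble_descriptors(w$mols, field_config(block_scaling = "none"))
  pts <- grid_points(d2$grid)
  set.seed(5)
  for (j in sample(ncol(d2$X), 25)) {
    f <- d2$columns$field[j]; gi <- d2$columns$grid_index[j]
    direct <- vapply(w$mols, similarity_index, numeric(1),
                     points = pts[gi, , drop = FALSE], field = f,
                     config = field_config())
    expect_equal(unname(d2$X[, j]), unname(direct), tolerance = 1e-12)
  }

  # comsia block scaling equalizes per-block total variance
  d3 <- assemble_descriptors(w$mols, field_config(block_scaling = "comsia_std"))
  tv <- vapply(duotox:::FIELD_NAMES, function(f) {
    sum(apply(d3$X[, d3$columns$field == f, drop = FALSE], 2, var))
  }, numeric(1))
  expect_true(all(abs(tv - 1) < 1e-9))

  # dropping everything is a configuration error
  expect_error(
    assemble_descriptors(list(toy, toy2), field_config(column_drop_sigma = 1)),
    class = "duotox_config_error")
})

test_that("translating molecules and grid together leaves descriptors unchanged", {
  w <- small_world()
  cfg <- field_config()
  d <- assemble_descriptors(w$mols, cfg)
  shift <- c(2.5, -1, 4)
  moved <- lapply(w$mols, function(m) {
    m$atoms$x <- m$atoms$x + shift[1]
    m$atoms$y <- m$atoms$y + shift[2]
    m$atoms$z <- m$atoms$z + shift[3]
    m
  })
  g2 <- d$grid; g2$origin <- g2$origin + shift
  d2 <- assemble_descriptors(moved, cfg, grid = g2)
  expect_equal(d2$X, d$X, tolerance = 1e-9, ignore_attr = TRUE)
})
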