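test_that("canonical strokes yield the expected pixel-node classification", {
  # straight 10-pixel line: two endpoints, eight bulk pixels, one cluster
  line <- matrix(0, 5, 14); line[3, 3:12] <- 1
  g <- build_skeleton_graph(line)
  cen <- degree_census(g)
  expect_equal(cen$x1, 2L)
  expect_equal(sum(g$pixels$degree == 2L), 8L)
  expect_equal(cen$n_clusters, 1L)
  expect_equal(cen$largest_cluster_fraction, 1)

  # "T" junction: one degree-3 node, three tips
  tee <- matrix(0, 10, 11); tee[2, 2:10] <- 1; tee[2:8, 6] <- 1
  cen <- degree_census(build_skeleton_graph(tee))
  expect_equal(c(cen$x1, cen$x3, cen$x4), c(3L, 1L, 0L))

  # "+" crossing: one apparent degree-4 node
  cross <- matrix(0, 11, 11); cross[6, 2:10] <- 1; cross[2:10, 6] <- 1
  cen <- degree_census(build_skeleton_graph(cross))
  expect_equal(c(cen$x1, cen$x3, cen$x4), c(4L, 0L, 1L))
  expect_equal(cen$fraction_k4_apparent, 100)

  # rectangular loop: no tips, no branches, one cluster
  loop <- matrix(0, 9, 9)
  loop[2, 2:8] <- 1; loop[8, 2:8] <- 1; loop[2:8, 2] <- 1; loop[2:8, 8] <- 1
  cen <- degree_census(build_skeleton_graph(loop))
  expect_equal(c(cen$x1, cen$x3, cen$x4, cen$n_clusters), c(0L, 0L, 0L, 1L))
})

test_that("diagonal steps in a line raise no spurious branches", {
  st <- matrix(0, 7, 8)
  st[rbind(c(2, 2), c(2, 3), c(3, 3), c(3, 4), c(4, 4), c(4, 5))] <- 1
  cen <- degree_census(build_skeleton_graph(st))
  expect_equal(c(cen$x1, cen$x3, cen$x4, cen$n_clusters), c(2L, 0L, 0L, 1L))
})

test_that("non-binary images are rejected", {
  expect_error(build_skeleton_graph(matrix(c(0, 0.5, 1, 1), 2)), "binary")
  expect_error(build_skeleton_graph("not a matrix"), "matrix")
})

test_that("overlay correction reproduces the worked example and sane identities", {
  expect_equal(overlay_correction(17.0, 0.80, 0.07), 96, tolerance = 0.005)
  expect_equal(overlay_correction(0, 0.5, 0), 100)
  expect_equal(overlay_correction(50, 0, 0), 50)
  expect_error(overlay_correction(120, 0.5, 0.1), "percentage")
  expect_error(overlay_correction(10, 1.5, 0.1), "fractions")
})

test_that("overlay correction is monotone in its inputs", {
  shares <- vapply(seq(0, 60, by = 5),
                   function(f) overlay_correction(f, 0.8, 0.07), numeric(1))
  expect_true(all(diff(shares) < 0))  # more apparent k4 lowers the k3 share
  rates <- vapply(seq(0, 1, by = 0.1),
                  function(a) overlay_correction(17, a, 0.07), numeric(1))
  expect_true(all(diff(rates) > 0))   # a larger k4 artifact rate raises it
})

test_that("synthetic skeletons round-trip through the census", {
  set.seed(55)
  for (seed in 1:30) {
    spec <- list(n_open = sample(0:5, 1), n_t = sample(0:4, 1),
                 n_loop = sample(0:3, 1), n_cross = sample(0:2, 1))
    syn <- generate_synthetic_skeleton(spec$n_open, spec$n_t, spec$n_loop,
                                       spec$n_cross, canvas = 128,
                                       seed = seed, allow_overlap = TRUE)
    cen <- degree_census(build_skeleton_graph(syn$image))
    expect_identical(cen$x1, syn$truth$x1)
    expect_identical(cen$x3, syn$truth$x3)
    expect_identical(cen$x4, syn$truth$x4_apparent)
    expect_identical(cen$n_clusters, syn$truth$n_clusters)
  }
})

test_that("crossing strokes must be requested explicitly", {
  expect_error(generate_synthetic_skeleton(1, 0, 0, n_cross = 2,
                                           allow_overlap = FALSE),
               "allow_overlap")
})

test_that("skeleton images survive PNG and TIFF round trips", {
  syn <- generate_synthetic_skeleton(3, 2, 1, 1, seed = 4, allow_overlap = TRUE)
  for (ext in c(".png", ".tiff")) {
    f <- withr::local_tempfile(fileext = ext)
    write_skeleton_image(syn$image, f)
    back <- read_skeleton_image(f)
    expect_equal(back, syn$image)
  }
})
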