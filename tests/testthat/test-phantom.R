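test_that("reference phantom places materials where the layout says", {
  ph <- acc_phantom()
  center <- phantom_material_at(ph, c(0, 0, 0))
  expect_equal(center$name, "water")
  expect_equal(center$mu_t, 0.028)
  expect_equal(center$beta * center$mu_s, 0.0140)          # mu_s_r
  expect_equal((1 - center$beta) * center$mu_s, 0.1680)    # mu_s_c

  c4 <- phantom_material_at(ph, c(2.5, -2.5, 0))
  expect_equal(c4$name, "cube4")
  expect_equal(c4$mu_t, 0.028)
  expect_equal(c4$beta * c4$mu_s, 0.0520)
  expect_equal((1 - c4$beta) * c4$mu_s, 0.1300)

  out <- phantom_material_at(ph, c(0, 0, 10))
  expect_equal(out$mu_t + out$mu_s, 0)
})

test_that("phantom constructor rejects bad geometry", {
  w <- table1_materials()$water
  bg <- box_region(c(-5, -5, -2.5), c(5, 5, 2.5), w)
  expect_error(box_region(c(0, 0, 0), c(-1, 1, 1), w), "lo < hi")
  expect_error(phantom(bg, list(box_region(c(4, 4, -1), c(6, 5, 1), w))),
               "not contained")
  expect_error(
    phantom(bg, list(box_region(c(0, 0, 0), c(2, 2, 1), w),
                     box_region(c(1, 1, 0), c(3, 3, 1), w))),
    "overlap")
})

test_that("ray tracing partitions chords exactly at box faces", {
  ph <- acc_phantom()

  ## axial ray missing every cube
  s1 <- trace_segments(ph, c(0.3, 0.3, -10), c(0, 0, 1))
  expect_equal(nrow(s1), 1)
  expect_equal(s1$material, "water")
  expect_equal(s1$length, 5)

  ## axial ray through the center of cube 1
  s2 <- trace_segments(ph, c(-2.5, 2.5, -10), c(0, 0, 1))
  expect_equal(s2$material, c("water", "cube1", "water"))
  expect_equal(s2$length, c(2, 1, 2))
  expect_equal(sum(s2$length), 5)

  ## 45-degree ray in a cube-free plane: chord 5 * sqrt(2)
  d <- c(0, 1, 1) / sqrt(2)
  s3 <- trace_segments(ph, c(-4, -4, -5), d)
  expect_equal(s3$material, "water")
  expect_equal(sum(s3$length), 5 * sqrt(2), tolerance = 1e-12)

  ## miss
  expect_equal(nrow(trace_segments(ph, c(20, 0, -10), c(0, 0, 1))), 0)
})

test_that("segment lengths sum to the background chord on random rays", {
  ph <- acc_phantom()
  bg <- ph$background
  ## independent slab-method oracle
  chord <- function(o, d) {
    t0 <- -Inf; t1 <- Inf
    for (i in 1:3) {
      if (d[i] == 0) { if (o[i] < bg$lo[i] || o[i] > bg$hi[i]) return(0) }
      else {
        tt <- sort(c((bg$lo[i] - o[i]) / d[i], (bg$hi[i] - o[i]) / d[i]))
        t0 <- max(t0, tt[1]); t1 <- min(t1, tt[2])
      }
    }
    max(t1 - max(t0, 0), 0)
  }
  set.seed(7)
  for (i in 1:50) {
    o <- c(runif(2, -8, 8), -10)
    d <- c(runif(2, -0.4, 0.4), 1)
    d <- d / sqrt(sum(d^2))
    segs <- trace_segments(ph, o, d)
    expect_equal(sum(segs$length), chord(o, d), tolerance = 1e-10)
  }
})

test_that("free-path sampling inverts the optical-depth equation", {
  w <- table1_materials()$water           # mu_t + mu_s = 0.21
  slab <- phantom(box_region(c(-5, -5, -2.5), c(5, 5, 2.5), w))

  ## forced xi = exp(-0.21 * 5): interaction exactly at the exit face
  hit <- sample_interaction(slab, c(0, 0, -10), c(0, 0, 1),
                            xi = exp(-1.05))
  expect_false(hit$escaped)
  expect_equal(hit$position[3], 2.5, tolerance = 1e-9)
  expect_equal(hit$material$name, "water")

  ## any smaller optical depth escapes
  expect_true(sample_interaction(slab, c(0, 0, -10), c(0, 0, 1),
                                 xi = exp(-1.06))$escaped)

  ## vacuum: always escapes
  vac <- phantom(box_region(c(-1, -1, -1), c(1, 1, 1),
                            material("vacuum", 0, 0, 0)))
  expect_true(sample_interaction(vac, c(0, 0, -5), c(0, 0, 1))$escaped)

  ## mean free path in effectively unbounded water = 1 / 0.21
  big <- phantom(box_region(c(-1, -1, 0), c(1, 1, 1e4), w))
  set.seed(11)
  n <- 4000
  depths <- vapply(seq_len(n), function(i)
    sample_interaction(big, c(0, 0, 0), c(0, 0, 1))$position[3], 0)
  mfp <- 1 / 0.21
  expect_lt(abs(mean(depths) - mfp), 3 * mfp / sqrt(n))
})

test_that("interaction depths follow the piecewise-exponential two-layer law", {
  ## 1 cm of a dense layer over 1 cm of water
  dense <- material("dense", 0.2, 0.6, 0.1)   # mu = 0.8
  water <- table1_materials()$water           # mu = 0.21
  ph <- phantom(box_region(c(-1, -1, 0), c(1, 1, 2), water),
                list(box_region(c(-1, -1, 0), c(1, 1, 1), dense)))
  mu1 <- 0.8; mu2 <- 0.21
  set.seed(13)
  n <- 4000
  z <- vapply(seq_len(n), function(i) {
    h <- sample_interaction(ph, c(0, 0, -1), c(0, 0, 1))
    if (h$escaped) NA_real_ else h$position[3]
  }, 0)
  z <- z[!is.na(z)]
  p_int <- 1 - exp(-mu1 - mu2)
  cdf <- function(q) ifelse(q < 1, 1 - exp(-mu1 * q),
                            1 - exp(-mu1 - mu2 * (q - 1))) / p_int
  ks <- suppressWarnings(stats::ks.test(z, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("phantom and material-table files round-trip", {
  ph <- acc_phantom()
  f <- tempfile(fileext = ".yaml")
  write_phantom(ph, f)
  back <- read_phantom(f)
  expect_equal(back, ph, tolerance = 1e-12)

  mats <- table1_materials()
  g <- tempfile(fileext = ".tsv")
  write_material_table(mats, g)
  back_m <- read_material_table(g)
  expect_equal(names(back_m), names(mats))
  expect_equal(back_m$cube3$beta, mats$cube3$beta, tolerance = 1e-12)

  expect_error(read_material_table(
    writeLines_path <- {
      p <- tempfile(); writeLines("name\tfoo\nx\t1", p); p
    }), "columns")
})
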