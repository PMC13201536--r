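test_that("epidermis detection keeps superficial patches only", {
  set.seed(3)
  strip <- data.frame(cell_id = sprintf("k%02d", 1:50),
                      x_um = seq(0, 980, length.out = 50),
                      y_um = runif(50, 0, 20),
                      true_type = "keratinocyte")
  dermis <- data.frame(cell_id = sprintf("f%02d", 1:60),
                       x_um = runif(60, 0, 1000),
                       y_um = runif(60, 100, 500),
                       true_type = "fibroblast")
  follicle <- data.frame(cell_id = sprintf("h%02d", 1:15),
                         x_um = runif(15, 480, 520),
                         y_um = runif(15, 380, 420),
                         true_type = "keratinocyte")
  nine <- data.frame(cell_id = sprintf("n%02d", 1:9),
                     x_um = runif(9, 700, 720),
                     y_um = runif(9, 0, 15),
                     true_type = "keratinocyte")
  # place the 9-cell group far from the strip so it forms its own patch
  nine$y_um <- nine$y_um + 600
  cells <- rbind(strip, dermis, follicle, nine)
  epi <- detect_epidermis(cells, link_radius_um = 30, min_patch = 10)
  expect_setequal(epi$cell_ids, strip$cell_id)
  # all keratinocytes mid-dermis: no layer above the dermis
  expect_error(detect_epidermis(rbind(follicle, dermis)),
               "no epidermal layer")
})

test_that("epidermis distance matches the brute-force oracle", {
  epi_cells <- epi_line()
  epi <- detect_epidermis(epi_cells, link_radius_um = 15, min_patch = 10)
  q <- data.frame(cell_id = c("q1", "q2"),
                  x_um = c(500, 0), y_um = c(90, 240),
                  true_type = "fibroblast")
  d <- distance_to_epidermis(q, epi)
  brute <- vapply(seq_len(2), function(i)
    min(sqrt((q$x_um[i] - epi_cells$x_um)^2 +
               (q$y_um[i] - epi_cells$y_um)^2)), 0)
  expect_equal(unname(d), brute, tolerance = 1e-12)
  expect_equal(unname(d[1]), 50, tolerance = 5)
  # epidermal member distance is 0
  d_epi <- distance_to_epidermis(epi_cells, epi)
  expect_true(all(d_epi == 0))
})

test_that("distances are invariant under rigid rotation", {
  epi_cells <- epi_line(n = 51)
  q <- data.frame(cell_id = "q", x_um = 430, y_um = 180,
                  true_type = "fibroblast")
  rot <- function(df, th) {
    out <- df
    out$x_um <- df$x_um * cos(th) - df$y_um * sin(th)
    out$y_um <- df$x_um * sin(th) + df$y_um * cos(th)
    out
  }
  epi1 <- list(cell_ids = epi_cells$cell_id,
               points = as.matrix(epi_cells[, c("x_um", "y_um")]))
  class(epi1) <- "epidermis_model"
  re <- rot(epi_cells, 0.7)
  epi2 <- list(cell_ids = re$cell_id,
               points = as.matrix(re[, c("x_um", "y_um")]))
  class(epi2) <- "epidermis_model"
  expect_equal(unname(distance_to_epidermis(q, epi1)),
               unname(distance_to_epidermis(rot(q, 0.7), epi2)),
               tolerance = 1e-9)
})

test_that("compartment assignment applies the 100 um rule", {
  expect_identical(assign_compartment(50), "papillary")
  expect_identical(assign_compartment(150), "reticular")
  expect_identical(assign_compartment(100), "reticular")
  expect_error(assign_compartment(-1), "non-negative")
  d <- runif(50, 0, 200)
  comp <- assign_compartment(d)
  expect_true(all(d[comp == "papillary"] < 100))
  expect_true(all(d[comp == "reticular"] >= 100))
})

test_that("vessel patches are knn components of at least 3 cells", {
  trio <- data.frame(cell_id = c("a", "b", "c"),
                     x_um = c(0, 5, 10), y_um = c(0, 5, 0),
                     true_type = "endothelial")
  p <- detect_vessel_patches(trio)
  expect_length(p, 1)
  expect_setequal(p[[1]]$cell_ids, trio$cell_id)
  pair <- trio[1:2, ]
  expect_length(detect_vessel_patches(pair), 0)
})

test_that("patch components match the brute-force oracle", {
  set.seed(8)
  clump1 <- cbind(runif(20, 0, 40), runif(20, 0, 40))
  clump2 <- cbind(runif(20, 500, 540), runif(20, 0, 40))
  pts <- rbind(clump1, clump2)
  cells <- data.frame(cell_id = sprintf("e%02d", 1:40),
                      x_um = pts[, 1], y_um = pts[, 2],
                      true_type = "endothelial")
  patches <- detect_vessel_patches(cells, k = 10, min_size = 3,
                                   max_link_um = 30)
  oracle <- brute_patch_components(pts, k = 10, max_link = 30)
  keep <- table(oracle)
  big <- names(keep)[keep >= 3]
  oracle_sets <- lapply(big, function(ci)
    cells$cell_id[oracle == as.integer(ci)])
  got_sets <- lapply(patches, `[[`, "cell_ids")
  expect_identical(length(got_sets), length(oracle_sets))
  for (s in oracle_sets)
    expect_true(any(vapply(got_sets, setequal, TRUE, s)))
})

test_that("patch orientation measures the angle to the epidermis", {
  epi_cells <- epi_line()
  epi <- detect_epidermis(epi_cells, 15, 10)
  vert <- list(cell_ids = sprintf("v%d", 1:5),
               coords = cbind(500, seq(120, 180, length.out = 5)),
               centroid = c(500, 150))
  class(vert) <- "vessel_patch"
  res <- patch_orientation(vert, epi)
  expect_equal(res$angle_deg, 90)
  expect_true(res$perpendicular)
  horiz <- vert
  horiz$coords <- cbind(seq(470, 530, length.out = 5), 150)
  res2 <- patch_orientation(horiz, epi)
  expect_equal(res2$angle_deg, 0)
  expect_false(res2$perpendicular)
  # exactly 45 degrees is not flagged (strict >)
  diag45 <- vert
  diag45$coords <- cbind(seq(480, 520, length.out = 5),
                         seq(130, 170, length.out = 5))
  res3 <- patch_orientation(diag45, epi)
  expect_equal(res3$angle_deg, 45)
  expect_false(res3$perpendicular)
  # degenerate patch
  degen <- vert
  degen$coords <- cbind(rep(500, 5), rep(150, 5))
  expect_error(patch_orientation(degen, epi), "degenerate")
})

test_that("patch axis equals the total-least-squares line", {
  epi_cells <- epi_line()
  epi <- detect_epidermis(epi_cells, 15, 10)
  set.seed(6)
  for (i in 1:5) {
    th <- runif(1, 0, pi)
    t_axis <- runif(12, -40, 40)
    pts <- cbind(400 + t_axis * cos(th) + rnorm(12, 0, 2),
                 200 + t_axis * sin(th) + rnorm(12, 0, 2))
    patch <- list(cell_ids = sprintf("p%d", 1:12), coords = pts,
                  centroid = colMeans(pts))
    class(patch) <- "vessel_patch"
    res <- patch_orientation(patch, epi)
    # independent TLS oracle: minimize perpendicular SSE over angle
    sse <- function(a) {
      dvec <- c(cos(a), sin(a))
      cc <- sweep(pts, 2, colMeans(pts))
      sum((cc %*% c(-dvec[2], dvec[1]))^2)
    }
    opt <- optimize(sse, c(0, pi))$minimum
    tls_angle <- min(abs(opt %% pi), pi - (opt %% pi)) * 180 / pi
    expect_equal(res$angle_deg, tls_angle, tolerance = 0.01)
  }
})

test_that("kde maps integrate to the total weight", {
  one <- data.frame(x_um = 100, y_um = 100)
  m <- kde_map(one, weights = 1, bandwidth_um = 30,
               grid_spacing_um = 5)
  integral <- sum(m$z) * m$grid_spacing_um^2
  expect_equal(integral, 1, tolerance = 0.02)
  # peak at the cell
  peak <- which(m$z == max(m$z), arr.ind = TRUE)
  expect_equal(m$x[peak[1]], 100, tolerance = 5)
  expect_equal(m$y[peak[2]], 100, tolerance = 5)
  # zero weights give the zero map
  expect_true(all(kde_map(one, weights = 0, bandwidth_um = 30)$z == 0))
  # two distant unit cells: halves integrate to about 1 each
  two <- data.frame(x_um = c(0, 2000), y_um = c(0, 0))
  m2 <- kde_map(two, bandwidth_um = 30, grid_spacing_um = 5)
  total <- sum(m2$z) * 25
  expect_equal(total, 2, tolerance = 0.04)
  left <- m2$x < 1000
  expect_equal(sum(m2$z[left, ]) * 25, 1, tolerance = 0.04)
  expect_error(kde_map(one, weights = NaN), "finite")
})
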