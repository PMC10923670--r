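test_that("rectangle mesh is valid and fully tagged", {
  m <- straight_mesh(L = 6, h = 0.5, ny = 8)
  v <- validate_mesh(m)
  expect_length(v$violations, 0)
  expect_gt(v$min_area, 0)
  expect_equal(v$euler, 1)
  ## tagged boundary lengths reconstruct the perimeter
  len <- function(tag) {
    b <- m$boundary[m$boundary$tag == tag, ]
    sum(sqrt((m$coords[b$n1, 1] - m$coords[b$n2, 1])^2 +
               (m$coords[b$n1, 2] - m$coords[b$n2, 2])^2))
  }
  expect_equal(len("inlet"), 2)
  expect_equal(len("outlet"), 2)
  expect_equal(len("wall"), 12)
  expect_true(all(vesselfem:::tri_signed_area(m) > 0))
})

test_that("lesion meshes refine at lesions and resolve the throat", {
  g <- small_stenosis_geom()
  m <- mesh_channel(g, h_far = 0.5, h_lesion = 0.2, ny = 8)
  expect_length(validate_mesh(m)$violations, 0)
  ## >= 6 element layers across the throat (rows span the gap)
  expect_gte(m$grid$ny, 6)
  ## axial spacing near the throat is finer than far upstream
  dx <- diff(m$grid$xcols)
  mids <- (m$grid$xcols[-1] + m$grid$xcols[-length(m$grid$xcols)]) / 2
  expect_lt(mean(dx[mids > 6 & mids < 9]), 0.6 * mean(dx[mids < 3]))
  ## generation is deterministic
  m2 <- mesh_channel(g, h_far = 0.5, h_lesion = 0.2, ny = 8)
  expect_identical(m$coords, m2$coords)
  expect_identical(m$tri, m2$tri)
  expect_error(mesh_channel(g, h_far = 0.5, h_lesion = 0.6, ny = 8),
               "h_lesion")
  expect_error(mesh_channel(g, h_far = 2, h_lesion = 2, ny = 8), "columns")
})

test_that("mesh is exactly mirror-symmetric about the channel axis", {
  m <- small_mesh(small_aneurysm_geom())
  mm <- mirror_map(m)
  expect_false(anyNA(mm))
  expect_equal(m$coords[mm, 2], -m$coords[, 2])
  expect_equal(m$coords[mm, 1], m$coords[, 1])
})

test_that("halving h at least quadruples elements in refined regions", {
  g <- small_stenosis_geom()
  m1 <- mesh_channel(g, h_far = 0.5, h_lesion = 0.25)
  m2 <- mesh_channel(g, h_far = 0.25, h_lesion = 0.125)
  expect_gte(m2$n_elem / m1$n_elem, 3.5)
})

test_that("validate_mesh flags a perturbed midside node", {
  m <- straight_mesh(L = 2, h = 0.5, ny = 6)
  m$coords[m$tri[1, 4], ] <- m$coords[m$tri[1, 4], ] + c(0.05, 0)
  v <- validate_mesh(m)
  expect_true(any(grepl("midside", v$violations)))
})

test_that("MSH v2.2 writing round-trips bit-exactly and keeps tags", {
  m <- straight_mesh(L = 3, h = 0.5, ny = 6)
  f <- tempfile(fileext = ".msh")
  write_mesh(m, f)
  m2 <- read_mesh(f)
  expect_identical(m2$coords[, 1], m$coords[, 1])
  expect_identical(m2$coords[, 2], m$coords[, 2])
  expect_equal(m2$tri, m$tri, ignore_attr = TRUE)
  expect_equal(sort(table(m2$boundary$tag)), sort(table(m$boundary$tag)))
  ## ordering stability across two writes
  f2 <- tempfile(fileext = ".msh")
  write_mesh(m, f2)
  expect_identical(readLines(f), readLines(f2))
  expect_error(write_mesh(m, tempfile(fileext = ".foo")), "unsupported")
})

test_that("VTU export carries the mesh and point fields", {
  m <- straight_mesh(L = 2, h = 0.5, ny = 6)
  f <- tempfile(fileext = ".vtu")
  write_vtu(m, f, point_data = list(demo = seq_len(m$n_nodes)))
  txt <- readLines(f)
  expect_true(any(grepl(sprintf('NumberOfPoints="%d"', m$n_nodes), txt)))
  expect_true(any(grepl(sprintf('NumberOfCells="%d"', m$n_elem), txt)))
  expect_true(any(grepl('Name="demo"', txt)))
})
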