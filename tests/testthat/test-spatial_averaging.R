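path_topology <- function(n) {
  topology(mass = rep(10, n),
           bonds = data.frame(i = seq_len(n - 1), j = 2:n, r0 = 1, fc = 1))
}

test_that("bonded neighbourhoods walk the bond graph to the right depth", {
  top <- path_topology(6)
  nb2 <- bonded_neighborhoods(top, 2)
  expect_equal(nb2$sets[[1]], c(1L, 2L, 3L))        # self + 1-2 + 1-3
  expect_equal(nb2$sets[[3]], 1:5)
  nb3 <- bonded_neighborhoods(top, 3)
  expect_equal(nb3$sets[[1]], 1:4)                  # adds the 1-4 atom
  # isolated atom keeps a singleton set
  iso <- topology(mass = c(1, 1, 1),
                  bonds = data.frame(i = 1, j = 2, r0 = 1, fc = 1))
  expect_equal(bonded_neighborhoods(iso, 2)$sets[[3]], 3L)
  # sets from an undirected graph are symmetric
  for (i in 1:6) for (j in nb2$sets[[i]]) {
    expect_true(i %in% nb2$sets[[j]])
  }
})

test_that("set averaging passes uniform motion and cancels opposite motion", {
  top <- path_topology(2)
  nb <- bonded_neighborhoods(top, 2)
  # singleton behaviour via type-1 dispatch
  q <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  out <- spatial_average(q, q, 1, top$mass)
  expect_identical(out$p_hat, q)
  # anti-parallel momenta in a shared set cancel exactly
  u <- matrix(c(1, -1, 0.5, -0.5, 2, -2), 2, 3)
  expect_true(all(average_over_sets(nb, top$mass, u) == 0))
  # uniform velocity field: q_hat_i = m_i u  (masses 1, 2, 1)
  top3 <- topology(mass = c(1, 2, 1),
                   bonds = data.frame(i = 1:2, j = 2:3, r0 = 1, fc = 1))
  nb3 <- bonded_neighborhoods(top3, 2)
  uvec <- c(0.3, -0.2, 1)
  q3 <- outer(top3$mass, uvec)
  got <- average_over_sets(nb3, top3$mass, q3)
  expect_equal(got, q3, tolerance = 1e-14)
})

test_that("grid projection deposits trilinear weights correctly", {
  dL <- 5
  # single atom exactly on a grid point: full weight at one point
  p <- matrix(c(0.4, 0, 0), 1, 3)
  fld <- grid_project(matrix(0, 1, 3), m = 2, p_avg = p,
                      dF = matrix(0, 1, 3), dL = dL)
  occ <- which(fld$mass > 0)
  expect_length(occ, 1L)
  expect_equal(fld$mass[occ], 2)
  expect_equal(fld$v[occ, ], c(0.2, 0, 0))   # v = p / m
  # atom at a cell centre: each of the 8 corners gets 1/8 of the mass
  fld <- grid_project(matrix(dL / 2, 1, 3), m = 8, p_avg = p,
                      dF = matrix(0, 1, 3), dL = dL)
  expect_equal(sort(unique(round(fld$mass[fld$mass > 0], 12))), 1)
  expect_equal(sum(fld$mass > 0), 8L)
  # two equal atoms mirrored about a grid point with opposite momenta:
  # the corners both atoms touch receive equal and opposite deposits
  delta <- 1.3
  pos2 <- rbind(c(-delta, 1.0, 2.0), c(delta, 1.0, 2.0))
  p2 <- rbind(c(0.3, -0.1, 0.2), -c(0.3, -0.1, 0.2))
  fld <- grid_project(pos2, m = c(4, 4), p_avg = p2,
                      dF = matrix(0, 2, 3), dL = dL)
  occ <- which(fld$mass > 0)
  ix <- (occ - 1) %% fld$dims[1]
  xcoord <- fld$origin[1] + ix * dL
  shared <- occ[xcoord == 0]   # the mirror plane both atoms touch
  expect_equal(length(shared), 4L)
  expect_lt(max(abs(fld$v[shared, ])), 1e-12)
  # degenerate mirror (coincident atoms): the whole field cancels
  pos3 <- rbind(c(1.1, 0.9, 2.2), c(1.1, 0.9, 2.2))
  fld3 <- grid_project(pos3, m = c(4, 4), p_avg = p2,
                       dF = matrix(0, 2, 3), dL = dL)
  expect_lt(max(abs(fld3$v)), 1e-12)
})

test_that("project-then-interpolate is exact for single atoms and uniform fields", {
  set.seed(5)
  # one atom anywhere: identity
  for (rep_ in 1:5) {
    pos <- matrix(runif(3, -20, 20), 1, 3)
    p <- matrix(rnorm(3), 1, 3)
    dF <- matrix(rnorm(3), 1, 3)
    out <- spatial_average(p, dF, 4, m = 7, positions = pos, dL = 5)
    expect_equal(out$p_hat, p, tolerance = 1e-12)
    expect_equal(out$dF_hat, dF, tolerance = 1e-12)
  }
  # uniform velocity field: p_hat_i = m_i u for every averaging type
  fix <- small_chain_fixture()
  m <- fix$topology$mass
  uvec <- c(0.4, -0.1, 0.25)
  p <- outer(m, uvec)
  for (ty in 1:4) {
    nb <- if (ty %in% 2:3) bonded_neighborhoods(fix$topology, ty) else NULL
    out <- spatial_average(p, p, ty, m, positions = fix$positions,
                           neigh = nb, dL = 5)
    expect_equal(out$p_hat, p, tolerance = 1e-10)
  }
})

test_that("trilinear weights form a partition of unity", {
  set.seed(9)
  pos <- matrix(runif(60, -13, 13), 20, 3)
  # a field that is 1 at every grid point must interpolate to exactly 1
  fld <- grid_project(pos, m = rep(1, 20), p_avg = matrix(0, 20, 3),
                      dF = matrix(0, 20, 3), dL = 5)
  fld$v <- matrix(1, nrow(fld$v), 3)
  fld$a <- matrix(1, nrow(fld$a), 3)
  out <- grid_interpolate(fld, pos, m = rep(1, 20))
  expect_lt(max(abs(out$p_hat - 1)), 1e-12)
})

test_that("set averages are convex combinations of the inputs", {
  fix <- small_chain_fixture(seed = 31)
  m <- fix$topology$mass
  set.seed(2)
  p <- matrix(rnorm(length(m) * 3), ncol = 3) * m
  for (ty in 2:3) {
    nb <- bonded_neighborhoods(fix$topology, ty)
    out <- average_over_sets(nb, m, p)
    vel <- out / m
    v_in <- p / m
    for (i in seq_along(m)) {
      set <- nb$sets[[i]]
      for (c_ in 1:3) {
        expect_gte(vel[i, c_], min(v_in[set, c_]) - 1e-12)
        expect_lte(vel[i, c_], max(v_in[set, c_]) + 1e-12)
      }
    }
  }
})

test_that("the dispatcher validates its inputs", {
  expect_error(spatial_average(matrix(0, 1, 3), matrix(0, 1, 3), 5, 1),
               "unknown")
  expect_error(spatial_average(matrix(0, 1, 3), matrix(0, 1, 3), 4, 1,
                               positions = matrix(0, 1, 3), dL = -1),
               "dL")
  expect_error(spatial_average(matrix(0, 1, 3), matrix(0, 1, 3), 2, 1),
               "neighbourhood")
  # a rigidly translating bonded dimer keeps its momenta under type 2
  top <- path_topology(2)
  nb <- bonded_neighborhoods(top, 2)
  p <- outer(top$mass, c(1, 1, -2))
  out <- spatial_average(p, p, 2, top$mass, neigh = nb)
  expect_equal(out$p_hat, p, tolerance = 1e-14)
})
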