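test_that("single-linkage clustering matches the brute-force oracle", {
  box <- c(20, 20, 20)
  # two beads across / within the cutoff
  expect_identical(find_clusters(rbind(c(1, 1, 1), c(2.4, 1, 1)), box, 1.5),
                   c(1L, 1L))
  expect_identical(find_clusters(rbind(c(1, 1, 1), c(2.6, 1, 1)), box, 1.5),
                   c(1L, 2L))
  # chain of beads spaced 1 sigma links into one cluster
  chain <- cbind(seq(1, 15, by = 1), 5, 5)
  expect_identical(unique(find_clusters(chain, box, 1.5)), 1L)
  # periodic wrap links across the boundary
  expect_identical(find_clusters(rbind(c(0.3, 5, 5), c(19.8, 5, 5)), box, 1.5),
                   c(1L, 1L))

  # sparse gas: no percolation, and labels agree with an R union-find oracle
  set.seed(31)
  n <- 400
  pos <- matrix(runif(3 * n), n, 3) %*% diag(box)  # density 0.05
  labels <- find_clusters(pos, box, 1.5)
  expect_lt(max(tabulate(labels)), n / 4)
  oracle_labels <- local({
    pairs <- brute_force_pairs(pos, box, 1.5)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    vapply(seq_len(n), find, integer(1))
  })
  # same partition (labels may differ, co-membership must not)
  split_a <- unname(vapply(split(seq_len(n), labels), paste, character(1),
                           collapse = ","))
  split_b <- unname(vapply(split(seq_len(n), oracle_labels), paste,
                           character(1), collapse = ","))
  expect_setequal(split_a, split_b)
})

test_that("constructed geometries classify into the expected morphology classes", {
  box <- c(20, 20, 20)
  line <- cbind(seq(2, 12, by = 0.8), 10, 10)
  m1 <- classify_morphology(line, box)
  expect_identical(m1$dominant$class, "strand")
  expect_equal(m1$dominant$d_e, 1, tolerance = 0.05)

  set.seed(1)
  th <- runif(250) * 2 * pi; r <- sqrt(runif(250)) * 4
  disc <- cbind(10 + r * cos(th), 10 + r * sin(th), 10 + rnorm(250, 0, 0.02))
  m2 <- classify_morphology(disc, box)
  expect_identical(m2$dominant$class, "in_plane_cluster")
  expect_equal(m2$dominant$d_e, 2, tolerance = 0.05)

  # laterally percolating slab, 8 sigma thick
  set.seed(2)
  slab <- cbind(runif(1500) * 20, runif(1500) * 20, 6 + runif(1500) * 8)
  m3 <- classify_morphology(slab, box)
  expect_identical(m3$dominant$class, "film_3d")
  expect_gt(m3$dominant$d_e, 2.7)
  expect_true(m3$clusters$percolating[which.max(m3$clusters$size)])

  # compact non-spanning blob
  set.seed(4)
  blob <- matrix(rnorm(600, 10, 1.2), 200, 3)
  m4 <- classify_morphology(blob, box, cutoff = 2)
  expect_identical(m4$dominant$class, "cluster_3d")

  # report prints its convention note
  expect_output(print(m3), "convention")
})

test_that("d_e never increases when a blob is flattened along z", {
  box <- c(30, 30, 30)
  set.seed(3)
  blob <- matrix(rnorm(900, 15, 2), 300, 3)
  des <- vapply(c(1, 0.8, 0.5, 0.25, 0.1, 0.02), function(s) {
    b <- blob
    b[, 3] <- 15 + (b[, 3] - 15) * s
    classify_morphology(b, box, cutoff = 3)$dominant$d_e
  }, numeric(1))
  expect_true(all(diff(des) <= 1e-9))
  expect_equal(des[1], 3, tolerance = 0.05)
  expect_lt(des[length(des)], 2.2)
})

test_that("classification is invariant under translation and relabeling", {
  box <- c(20, 20, 20)
  set.seed(6)
  th <- runif(200) * 2 * pi; r <- sqrt(runif(200)) * 4
  disc <- cbind(10 + r * cos(th), 10 + r * sin(th), 10 + rnorm(200, 0, 0.02))
  m0 <- classify_morphology(disc, box)
  # rigid translation, including a box-wrapping shift
  for (shift in list(c(3, -2, 5), c(15, 15, 15))) {
    moved <- sweep(disc, 2, shift, `+`) %% 20
    m <- classify_morphology(moved, box)
    expect_identical(m$dominant$class, m0$dominant$class)
    expect_equal(m$dominant$d_e, m0$dominant$d_e, tolerance = 1e-6)
  }
  # permuting the beads changes nothing
  perm <- sample(nrow(disc))
  mp <- classify_morphology(disc[perm, ], box)
  expect_identical(mp$dominant$class, m0$dominant$class)
  expect_equal(mp$dominant$d_e, m0$dominant$d_e, tolerance = 1e-9)
})
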