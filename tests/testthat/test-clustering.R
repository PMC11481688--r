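test_that("temporal grouping follows the frame-gap/distance chain rule", {
  # two blinks at the same spot, frames 1 and 3: within gap 2 -> 1 molecule
  tbl <- loc_table(frame = c(1, 3), x = c(0, 0), y = c(0, 0),
                   channel = c(1, 1))
  m <- group_temporally(tbl, frame_gap = 2, max_distance = 30)
  expect_identical(nrow(m), 1L)
  expect_identical(m$n_locs, 2L)
  expect_identical(m$first_frame, 1L)
  expect_identical(m$last_frame, 3L)

  # 31 nm apart on consecutive frames: just over the distance threshold
  tbl <- loc_table(frame = c(0, 1), x = c(0, 31), y = c(0, 0),
                   channel = c(1, 1))
  expect_identical(nrow(group_temporally(tbl)), 2L)
  # exactly 30 nm links (inclusive)
  tbl30 <- loc_table(frame = c(0, 1), x = c(0, 30), y = c(0, 0),
                     channel = c(1, 1))
  expect_identical(nrow(group_temporally(tbl30)), 1L)

  # identical coordinates, different channels: never merged
  tbl <- loc_table(frame = c(0, 0), x = c(5, 5), y = c(5, 5),
                   channel = c(1, 2))
  expect_identical(nrow(group_temporally(tbl)), 2L)

  # frames 0 and 4 with gap 2 (max step 3 frames) stay separate, but an
  # intermediate blink chains them
  far <- loc_table(frame = c(0, 4), x = c(0, 0), y = c(0, 0),
                   channel = c(1, 1))
  expect_identical(nrow(group_temporally(far)), 2L)
  chain <- loc_table(frame = c(0, 2, 4), x = c(0, 10, 0), y = c(0, 0, 0),
                     channel = c(1, 1, 1))
  expect_identical(nrow(group_temporally(chain)), 1L)

  expect_identical(nrow(group_temporally(loc_table(integer(0), numeric(0),
                                                   numeric(0), integer(0)))),
                   0L)
})

test_that("grouping conserves localizations and is order-independent", {
  set.seed(21)
  for (rep in 1:5) {
    n_mol <- 40
    centres <- data.frame(x = runif(n_mol, 0, 2e4), y = runif(n_mol, 0, 2e4),
                          channel = sample(1:2, n_mol, TRUE))
    rows <- do.call(rbind, lapply(seq_len(n_mol), function(i) {
      k <- 1 + rpois(1, 3)
      data.frame(frame = cumsum(c(sample(0:1400, 1), sample(1:3, k - 1, TRUE))),
                 x = centres$x[i] + rnorm(k, 0, 8),
                 y = centres$y[i] + rnorm(k, 0, 8),
                 channel = centres$channel[i])
    }))
    tbl <- loc_table(rows$frame, rows$x, rows$y, rows$channel)
    m <- group_temporally(tbl)
    expect_identical(sum(m$n_locs), nrow(tbl))
    expect_true(nrow(m) <= nrow(tbl))

    # permuting input rows yields the same partition (same multiset of
    # molecule signatures)
    perm <- sample(nrow(tbl))
    tblp <- loc_table(rows$frame[perm], rows$x[perm], rows$y[perm],
                      rows$channel[perm])
    mp <- group_temporally(tblp)
    sig <- function(mm) {
      s <- sprintf("%.6f_%.6f_%d_%d", mm$x, mm$y, mm$n_locs, mm$channel)
      sort(s)
    }
    expect_identical(sig(m), sig(mp))
  }
})

test_that("grouping is idempotent and monotone in max_distance", {
  set.seed(22)
  for (rep in 1:3) {
    # molecules well separated relative to the linking scale
    n_mol <- 30
    cx <- runif(n_mol, 0, 5e4); cy <- runif(n_mol, 0, 5e4)
    k <- 1 + rpois(n_mol, 4)
    idx <- rep(seq_len(n_mol), k)
    tbl <- loc_table(frame = unlist(lapply(k, function(kk)
                       cumsum(c(0, sample(1:3, kk - 1, TRUE))))),
                     x = cx[idx] + rnorm(length(idx), 0, 5),
                     y = cy[idx] + rnorm(length(idx), 0, 5),
                     channel = rep(1L, length(idx)))
    m1 <- group_temporally(tbl)
    # feed molecule positions back through grouping: nothing merges further
    tbl2 <- loc_table(frame = m1$first_frame, x = m1$x, y = m1$y,
                      channel = m1$channel)
    m2 <- group_temporally(tbl2)
    expect_identical(nrow(m2), nrow(m1))

    # molecule count never increases as max_distance grows
    counts <- vapply(c(10, 20, 30, 50, 80), function(d)
      nrow(group_temporally(tbl, max_distance = d)), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("cluster detection applies the strict >15-molecule rule", {
  set.seed(31)
  disc <- disc_points(16, 25)
  cl <- clusters_from_points(list(list(x = disc$x, y = disc$y, channel = 1)),
                             min_molecules = 15)
  expect_identical(nrow(cl$clusters), 1L)
  expect_identical(cl$clusters$n_molecules, 16L)

  disc15 <- disc_points(15, 25)
  cl15 <- clusters_from_points(list(list(x = disc15$x, y = disc15$y,
                                         channel = 1)), min_molecules = 15)
  expect_identical(nrow(cl15$clusters), 0L)

  # two 20-molecule groups 5 um apart form two clusters
  g1 <- disc_points(20, 40, 0, 0)
  g2 <- disc_points(20, 40, 5000, 0)
  cl2 <- clusters_from_points(list(list(x = g1$x, y = g1$y, channel = 1),
                                   list(x = g2$x, y = g2$y, channel = 2)),
                              min_molecules = 15)
  expect_identical(nrow(cl2$clusters), 2L)
  # clusters are cross-channel: per-channel counts sum to the total
  expect_identical(cl2$clusters$n_ch1 + cl2$clusters$n_ch2,
                   cl2$clusters$n_molecules)
})

test_that("cluster detection equals brute-force connected components", {
  set.seed(32)
  brute_components <- function(x, y, r) {
    n <- length(x)
    adj <- as.matrix(dist(cbind(x, y))) <= r
    comp <- rep(0L, n)
    cur <- 0L
    for (i in seq_len(n)) {
      if (comp[i] == 0L) {
        cur <- cur + 1L
        frontier <- i
        comp[i] <- cur
        while (length(frontier)) {
          nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) &
                        comp == 0L)
          comp[nb] <- cur
          frontier <- nb
        }
      }
    }
    comp
  }
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    x <- runif(n, 0, 3000); y <- runif(n, 0, 3000)
    r <- runif(1, 100, 400)
    mols <- data.frame(molecule = seq_len(n), x = x, y = y,
                       channel = sample(1:2, n, TRUE), n_locs = 1L,
                       first_frame = 0L, last_frame = 0L)
    cl <- detect_clusters(mols, link_radius = r, min_molecules = 0)
    bc <- brute_components(x, y, r)
    # same partition: cluster ids must be a relabelling of brute components
    expect_identical(length(unique(bc)), nrow(cl$clusters))
    tab <- table(bc, cl$molecules$cluster_id)
    expect_true(all(rowSums(tab > 0) == 1), all(colSums(tab > 0) == 1))
  }
})
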