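mk_profile <- function(chain, ct) {
  structure(list(residue_ids = chain$resno, residue_names = chain$resid,
                 averaged_ct = stats::setNames(ct, chain$resno),
                 hub = chain$resno[which.max(ct)]),
            class = "coupling_profile")
}

test_that("triad recipe: mutual contact and sequence separation both bind", {
  side <- 5
  tri <- rbind(c(0, 0, 0), c(side, 0, 0), c(side / 2, side * sqrt(3) / 2, 0))
  ch <- chain_from_xyz(tri, resno = c(1, 10, 20))
  cs <- find_triad_cliques(ch, cutoff = 6.2, min_separation = 4)
  expect_equal(nrow(cs$triads), 1L)
  expect_true(has_triad(cs, c(1, 10, 20)))

  ch2 <- chain_from_xyz(tri, resno = c(1, 2, 20)) # separation 1 < 4
  expect_equal(nrow(find_triad_cliques(ch2, 6.2, 4)$triads), 0L)

  # side 6.0 exceeds a 5.9 cutoff but not 6.0
  ch3 <- chain_from_xyz(tri * 6 / 5, resno = c(1, 10, 20))
  expect_equal(nrow(find_triad_cliques(ch3, 5.9)$triads), 0L)
  expect_equal(nrow(find_triad_cliques(ch3, 6.05)$triads), 1L)
})

test_that("triad enumeration equals the O(n^3) oracle", {
  for (s in c(1, 2)) {
    ch <- toy_chain("random_coil", 60, seed = s)
    got <- find_triad_cliques(ch, cutoff = 6.2, min_separation = 4)$triads
    want <- oracle_triads(ch$xyz, ch$resno, 6.2, 4)
    expect_equal(unname(got), unname(want))
  }
  # a compact blob yields many triads; verify against the oracle too
  ch <- toy_chain("clustered", 30, seed = 10)
  got <- find_triad_cliques(ch, cutoff = 6.4, min_separation = 4)$triads
  expect_equal(unname(got), unname(oracle_triads(ch$xyz, ch$resno, 6.4, 4)))
})

test_that("cutoff sweep is monotone and empty for sparse chains", {
  ch <- toy_chain("clustered", 35, seed = 4)
  sweep <- clique_cutoff_sweep(ch)
  counts <- vapply(sweep, function(cs) nrow(cs$triads), integer(1))
  expect_true(all(diff(counts) >= 0))
  for (i in seq_len(length(sweep) - 1)) {
    small <- sweep[[i]]$triads
    if (nrow(small) > 0) {
      for (r in seq_len(nrow(small))) {
        expect_true(has_triad(sweep[[i + 1]], small[r, ]))
      }
    }
  }
  # all residues > 7 A apart: nothing at any cutoff up to 6.4
  grid_xyz <- as.matrix(expand.grid(x = (0:2) * 8, y = (0:2) * 8, z = 0))
  far <- chain_from_xyz(grid_xyz)
  far_counts <- vapply(clique_cutoff_sweep(far),
                       function(cs) nrow(cs$triads), integer(1))
  expect_true(all(far_counts == 0L))
})

test_that("zero profile yields an empty pathway report with a warning", {
  ch <- toy_chain("helix", 15)
  prof <- mk_profile(ch, rep(0, 15))
  expect_warning(rep0 <- extract_pathways(ch, prof), "threshold")
  expect_length(rep0$path_residues, 0L)
  expect_equal(nrow(rep0$pair_table), 0L)
})

test_that("pair table matches brute-force enumeration on a forced triangle", {
  # three path residues mutually within 7.2 A, separations >= 10
  xyz <- rbind(c(0, 0, 0), c(6, 0, 0), c(3, 5, 0), c(100, 0, 0))
  ch <- chain_from_xyz(xyz, resno = c(1, 20, 40, 60))
  prof <- mk_profile(ch, c(1, 0.8, 0.6, 0))
  rep1 <- extract_pathways(ch, prof)
  expect_equal(rep1$path_residues, c(1L, 20L, 40L))
  expect_equal(nrow(rep1$pair_table), 3L)
  expect_equal(rep1$pair_table$i, c(1L, 1L, 20L))
  expect_equal(rep1$pair_table$j, c(20L, 40L, 40L))
  d13 <- sqrt(sum((xyz[1, ] - xyz[3, ])^2))
  expect_equal(rep1$pair_table$dist[2], d13, tolerance = 1e-12)
  # sub-threshold separation is excluded even when close in space
  rep2 <- extract_pathways(ch, prof, min_pair_separation = 25)
  expect_equal(nrow(rep2$pair_table), 1L) # only 1-40 pair survives (sep 39)
})

test_that("disjoint high-coupling clusters give two components with gates", {
  # two linear runs of path residues separated by > 7.2 A
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0),
               c(50, 0, 0), c(54, 0, 0), c(58, 0, 0))
  ch <- chain_from_xyz(xyz, resno = c(1, 2, 3, 30, 31, 32))
  prof <- mk_profile(ch, c(1, 0.9, 0.8, 0.7, 0.6, 0.5))
  repc <- extract_pathways(ch, prof, min_pair_separation = 1)
  expect_length(repc$components, 2L)
  expect_setequal(repc$components[[1]], c(1, 2, 3))
  expect_setequal(repc$components[[2]], c(30, 31, 32))
  # linear runs: extremities have subgraph degree 1
  expect_true(all(c(1, 3) %in% repc$gates[[1]]))
  expect_true(all(c(30, 32) %in% repc$gates[[2]]))
  expect_true(all(unlist(repc$gates) %in% repc$path_residues))
})

test_that("raising the coupling threshold never grows the path set", {
  ch <- toy_chain("clustered", 40, seed = 6)
  prof <- suppressWarnings(coupling_profile(ch))
  prev <- NULL
  for (thr in c(0.01, 0.02, 0.1, 0.5)) {
    cur <- suppressWarnings(
      extract_pathways(ch, prof, ct_threshold = thr))$path_residues
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("pair table is reproducible under input reordering", {
  ch <- toy_chain("clustered", 30, seed = 8)
  prof <- suppressWarnings(coupling_profile(ch))
  rep1 <- extract_pathways(ch, prof, min_pair_separation = 4)
  # write, re-read (file order preserved), recompute
  back <- load_calpha_chain(write_calpha_pdb(ch), "A")
  rep2 <- extract_pathways(back, suppressWarnings(coupling_profile(back)),
                           min_pair_separation = 4)
  expect_equal(rep1$pair_table$i, rep2$pair_table$i)
  expect_equal(rep1$pair_table$j, rep2$pair_table$j)
  expect_equal(rep1$pair_table$dist, rep2$pair_table$dist, tolerance = 1e-3)
})
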