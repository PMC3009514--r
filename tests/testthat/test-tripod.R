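test_that("triangle geometry: sides, law-of-cosines angles, degeneracies", {
  g <- triangle_geometry(c(0, 0, 0), c(8.5, 0, 0), c(4.25, 8.5 * sqrt(3) / 2, 0))
  expect_equal(g$sides, rep(8.5, 3), tolerance = 1e-9)
  expect_equal(g$angles, rep(60, 3), tolerance = 1e-9)
  expect_equal(sum(g$angles), 180, tolerance = 1e-6)

  col <- triangle_geometry(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))
  expect_equal(sort(col$angles), c(0, 0, 180), tolerance = 1e-6)

  iso <- triangle_geometry(c(0, 0, 0), c(10, 0, 0),
                           c(5, sqrt(7.1^2 - 25), 0))
  expect_equal(max(iso$angles), 89.53, tolerance = 0.01)

  expect_error(triangle_geometry(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
               "coincident")
})

test_that("fingerprint matching gates on sides, angles and rmsd", {
  fp <- tripod_fingerprint()
  # canonical triangle in an arbitrary pose matches with rmsd ~ 0
  set.seed(3)
  R <- ribomotif:::random_rotation()
  posed <- sweep(fp$points %*% t(R), 2, c(4, 5, 6), "+")
  m <- match_fingerprint(posed, fp)
  expect_true(m$accepted)
  expect_equal(m$best_rmsd, 0, tolerance = 1e-9)

  # permutation invariance
  for (p in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1))) {
    mp <- match_fingerprint(posed[p, ], fp)
    expect_true(mp$accepted)
    expect_equal(mp$best_rmsd, m$best_rmsd, tolerance = 1e-9)
  }

  # triangle with sides 8, 9, 12: the 12 A side is out of range
  x3 <- (8^2 + 9^2 - 12^2) / 16
  side12 <- rbind(c(0, 0, 0), c(8, 0, 0), c(x3, sqrt(81 - x3^2), 0))
  m2 <- match_fingerprint(side12, fp)
  expect_false(m2$accepted)
  expect_match(m2$reason, "side")

  # all sides inside (7, 10) but one angle far beyond 70 degrees
  xa <- (7.2^2 + 7.2^2 - 9.9^2) / (2 * 7.2)
  thin <- rbind(c(0, 0, 0), c(7.2, 0, 0), c(xa, sqrt(7.2^2 - xa^2), 0))
  m3 <- match_fingerprint(thin, fp)
  expect_false(m3$accepted)
  expect_match(m3$reason, "angle")

  # a side of exactly 10 falls outside the open side interval
  thin10 <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, sqrt(7.1^2 - 25), 0))
  m4 <- match_fingerprint(thin10, fp)
  expect_false(m4$accepted)

  degen <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_false(match_fingerprint(degen, fp)$accepted)
})

test_that("P-R-B filter truth table is exhaustive", {
  for (p in 0:3) for (r in 0:3) for (b in 0:3) {
    expect_identical(filter_prb(p, r, b), b >= r && r >= p && b > p,
                     info = paste(p, r, b))
  }
  expect_true(filter_prb(2, 4, 11))
  expect_false(filter_prb(1, 10, 5))
  expect_false(filter_prb(0, 0, 0))
})

test_that("knob detection keeps protruding apexes, one per residue", {
  sheet <- expand.grid(x = seq(-3, 3, by = 1.5), y = seq(-3, 3, by = 1.5))
  sheet_rows <- function() atom_row(paste0("C", seq_len(nrow(sheet))), "C",
                                    sheet$x, sheet$y, 0, "B", 1, "LEU")
  # two atoms protruding from the sheet in one residue: the more convex
  # one is that residue's single knob
  atoms <- rbind(
    sheet_rows(),
    atom_row("CB", "C", 0, 0, 2.5, "B", 2, "ARG"),
    atom_row("CG", "C", 0.3, 0, 1.7, "B", 2, "ARG"),
    atom_row("N1", "N", 0, 0, 5.7, "A", 9, "G"))
  m <- toy_model(atoms)
  s <- find_contacts(m)[[1]]
  knobs <- detect_knobs(s, m, compute_sasa(m))
  expect_equal(knobs$resid, "ARG")
  expect_equal(m$atoms$name[knobs$apex_row], "CB")
  expect_gt(knobs$convexity, 0.75)

  # a flat contacted patch yields no knob: the sheet atom under the
  # nucleotide has nothing protruding (contact reaches the centre only)
  flat <- toy_model(rbind(sheet_rows(),
                          atom_row("N1", "N", 0, 0, 4.4, "A", 9, "G")))
  s2 <- find_contacts(flat)[[1]]
  expect_equal(nrow(detect_knobs(s2, flat, compute_sasa(flat))), 0)
})

test_that("candidate enumeration is per-nucleotide 3-subsets of amino acids", {
  mk_site <- function(n_aa) {
    rna <- atom_row("N1", "N", 0, 0, 3, "A", 1, "G")
    prot <- do.call(rbind, lapply(seq_len(n_aa), function(k)
      atom_row("CB", "C", cos(2 * pi * k / n_aa) * 2,
               sin(2 * pi * k / n_aa) * 2, 1, "B", k, "ARG")))
    m <- toy_model(rbind(rna, prot))
    s <- find_contacts(m)[[1]]
    knobs <- data.frame(chain = "B", resno = seq_len(n_aa), insert = "",
                        resid = "ARG", apex_row = 1 + seq_len(n_aa),
                        x = prot$x, y = prot$y, z = prot$z,
                        convexity = 1, stringsAsFactors = FALSE)
    enumerate_candidates(knobs, s, m)
  }
  expect_length(mk_site(3), 1)
  expect_length(mk_site(4), 4)   # C(4,3)
  expect_length(mk_site(2), 0)
})

test_that("tripod search recovers planted sites and only those", {
  sc <- make_tripod_scene(synthetic_spec(seed = 1, noise_sigma = 0))
  hits <- search_tripods(sc$model)
  truth <- sc$truth
  expect_equal(nrow(hits), sum(truth$true))
  expect_setequal(hits$nt_resno, truth$nt_resno[truth$true])
  expect_equal(hits$prb[order(hits$nt_resno)],
               apply(truth[truth$true, c("p", "r", "b")], 1, paste,
                     collapse = "-"),
               ignore_attr = TRUE)
  expect_true(all(hits$hbond))
  expect_true(all(hits$match_rmsd <= tripod_fingerprint()$rmsd_max))

  # the inverted-composition decoy passes geometry but fails the filter
  counts <- attr(hits, "stage_counts")
  expect_equal(unname(counts["geometry_pass"]), sum(truth$true) + 1)
  expect_true(all(diff(unname(counts[c("triplets", "geometry_pass",
                                       "accepted")])) <= 0))
})

test_that("match acceptance is invariant under rigid motion", {
  sc <- make_tripod_scene(synthetic_spec(seed = 6, noise_sigma = 0))
  m2 <- sc$model
  set.seed(60)
  R <- ribomotif:::random_rotation()
  xyz <- as.matrix(m2$atoms[, c("x", "y", "z")])
  m2$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, c(7, -3, 11), "+")
  hits1 <- search_tripods(sc$model)
  hits2 <- search_tripods(m2)
  expect_equal(hits2$nt_resno, hits1$nt_resno)
  expect_equal(hits2$match_rmsd, hits1$match_rmsd, tolerance = 1e-6)
})
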