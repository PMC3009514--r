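two_molecule_model <- function(rna_xyz, prot_xyz, rna_name = "O2'",
                               prot_name = "N", rna_el = "O",
                               prot_el = "N") {
  n <- nrow(rna_xyz); m <- nrow(prot_xyz)
  toy_model(rbind(
    atom_row(rep_len(rna_name, n), rep_len(rna_el, n), rna_xyz[, 1],
             rna_xyz[, 2], rna_xyz[, 3], "A", seq_len(n), "G"),
    atom_row(rep_len(prot_name, m), rep_len(prot_el, m), prot_xyz[, 1],
             prot_xyz[, 2], prot_xyz[, 3], "B", seq_len(m), "ALA")))
}

test_that("contact classes follow the distance and element rules", {
  m <- two_molecule_model(matrix(c(0, 0, 0), 1), matrix(c(3, 0, 0), 1))
  s <- find_contacts(m)
  expect_length(s, 1)
  expect_equal(s[[1]]$pairs$klass, "hbond")

  m2 <- two_molecule_model(matrix(c(0, 0, 0), 1), matrix(c(4.2, 0, 0), 1),
                           rna_name = "C2", rna_el = "C",
                           prot_name = "CA", prot_el = "C")
  expect_equal(find_contacts(m2)[[1]]$pairs$klass, "vdw")

  # N/O pair beyond the H-bond cutoff is still a vdw contact
  m3 <- two_molecule_model(matrix(c(0, 0, 0), 1), matrix(c(4.0, 0, 0), 1))
  expect_equal(find_contacts(m3)[[1]]$pairs$klass, "vdw")

  m4 <- two_molecule_model(matrix(c(0, 0, 0), 1), matrix(c(6, 0, 0), 1))
  expect_length(find_contacts(m4), 0)

  prot_only <- toy_model(atom_row("CA", "C", 0, 0, 0, "B", 1, "ALA"))
  expect_error(find_contacts(prot_only), "not a protein-RNA complex")
})

test_that("grid neighbour search equals brute force on random toys", {
  for (seed in 1:3) {
    set.seed(seed)
    A <- matrix(runif(300, 0, 25), ncol = 3)
    B <- matrix(runif(300, 0, 25), ncol = 3)
    got <- ribomotif:::neighbor_pairs(A, B, 4.5)
    want <- brute_pairs(A, B, 4.5)
    key <- function(p) sort(paste(p$i, p$j))
    expect_equal(key(got), key(want))
  }
})

test_that("shrinking the contact cutoff never adds pairs", {
  set.seed(4)
  rna <- matrix(runif(60, 0, 10), ncol = 3)
  prot <- matrix(runif(60, 0, 10), ncol = 3)
  m <- two_molecule_model(rna, prot)
  cuts <- c(6, 4.5, 3.5, 2.5)
  npairs <- vapply(cuts, function(cd) {
    s <- find_contacts(m, contact_params(contact_dist = cd,
                                         hbond_dist = min(cd, 3.5)))
    if (length(s) == 0) 0L else nrow(s[[1]]$pairs)
  }, integer(1))
  expect_true(all(diff(npairs) <= 0))
})

test_that("P-R-B counts partition the pairs of a surface", {
  sc <- make_tripod_scene(synthetic_spec(seed = 5, noise_sigma = 0))
  s <- find_contacts(sc$model)[[1]]
  prb <- prb_counts(s, sc$model)
  expect_equal(sum(prb$p + prb$r + prb$b), nrow(s$pairs))
  # engineered counts recovered exactly, e.g. the 2-4-11 planted site
  row <- prb[prb$resno == sc$truth$nt_resno[sc$truth$tag == "true_eq"], ]
  expect_equal(unlist(row[, c("p", "r", "b")], use.names = FALSE),
               c(2, 4, 11))
  # nucleotides without pairs are absent
  expect_true(all(prb$p + prb$r + prb$b > 0))
})

test_that("per-nucleotide group counts follow the atom-name rule", {
  rna <- rbind(
    atom_row("P", "P", 0, 0, 0, "A", 1, "G"),
    atom_row("OP1", "O", 5, 0, 0, "A", 1, "G"),
    atom_row("C2'", "C", 10, 0, 0, "A", 1, "G"),
    atom_row("N1", "N", 15, 0, 0, "A", 1, "G"))
  prot <- atom_row("CA", "C", c(0, 5, 10, 15), 3, 0, "B", 1:4, "ALA")
  m <- toy_model(rbind(rna, prot))
  s <- find_contacts(m)[[1]]
  prb <- prb_counts(s, m)
  expect_equal(unlist(prb[1, c("p", "r", "b")], use.names = FALSE),
               c(2, 1, 1))
})

test_that("contact_area is additive over well-separated patches", {
  expect_equal(contact_area(integer(0), NULL), 0)
  iso <- toy_model(atom_row("O", "O", 0, 0, 0, "A", 1, "G"))
  expect_equal(contact_area(1, iso), 4 * pi * (1.52 + 1.5)^2,
               tolerance = 1e-9)
  set.seed(9)
  patch1 <- atom_row(paste0("C", 1:5), "C", runif(5, 0, 4), runif(5, 0, 4),
                     runif(5, 0, 4), "A", 1:5, "G")
  patch2 <- patch1
  patch2$x <- patch2$x + 50
  joint <- toy_model(rbind(patch1, patch2))
  a_joint <- contact_area(1:10, joint)
  a1 <- contact_area(1:5, toy_model(patch1))
  a2 <- contact_area(1:5, toy_model(patch2))
  expect_equal(a_joint, a1 + a2, tolerance = 0.01)
})
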