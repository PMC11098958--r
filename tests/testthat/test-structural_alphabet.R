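test_that("fragmentize yields n-3 fragments named by first residue", {
  expect_equal(nrow(fragmentize(toy_topology(100))), 97L)
  expect_equal(nrow(fragmentize(toy_topology(4))), 1L)
  expect_error(fragmentize(toy_topology(3)), "fewer than 4")

  # author numbering is preserved: a fragment starting at residue 115
  # covers residues 115..118
  atoms <- data.frame(atom = "CA", resno = 115:124, resid = "ALA",
                      chain = "A", stringsAsFactors = FALSE)
  topo <- allopath:::topology_from_atoms(atoms)
  fr <- fragmentize(topo)
  expect_equal(fr$fragment[1], 115)
  expect_equal(fr$fragment, 115:121)

  # chains never share fragments
  atoms2 <- rbind(atoms, transform(atoms, chain = "B"))
  topo2 <- allopath:::topology_from_atoms(atoms2)
  fr2 <- fragmentize(topo2)
  expect_equal(nrow(fr2), 14L)
  expect_equal(table(fr2$chain)[["A"]], 7L)
})

test_that("fragment descriptors match analytic cases and the bio3d oracle", {
  sq <- fragment_descriptors(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  expect_equal(c(sq$theta1, sq$theta2, sq$tau), c(90, 90, 0), tolerance = 1e-12)
  zz <- fragment_descriptors(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)))
  expect_equal(abs(zz$tau), 180, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:20) {
    m <- matrix(rnorm(12, sd = 3), 4, 3)
    got <- fragment_descriptors(m)$tau
    want <- bio3d::torsion.xyz(as.vector(t(m)), atm.inc = 4)
    expect_equal(got, as.numeric(want), tolerance = 1e-9)
  }
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(fragment_descriptors(collinear), "collinear")
})

test_that("angle-built fragments reproduce their angles exactly", {
  set.seed(6)
  for (i in 1:15) {
    th1 <- runif(1, 40, 170); th2 <- runif(1, 40, 170)
    ta <- runif(1, -179, 180)
    d <- fragment_descriptors(fragment_from_angles(th1, th2, ta))
    expect_equal(c(d$theta1, d$theta2, d$tau), c(th1, th2, ta),
                 tolerance = 1e-9)
  }
})

test_that("state assignment recovers exact canonical fragments under rigid motion", {
  alp <- synthetic_alphabet(8)
  set.seed(7)
  n_fr <- 6
  co <- array(0, c(n_fr, 4, 3))
  truth <- sample(1:8, n_fr, replace = TRUE)
  for (f in seq_len(n_fr)) {
    R <- random_rotation()
    co[f, , ] <- alp$coords[[truth[f]]] %*% t(R) +
      matrix(rnorm(3, 0, 10), 4, 3, byrow = TRUE)
  }
  tr <- trajectory(co, toy_topology(4))
  for (m in c("rmsd_local_fit", "descriptor_nearest")) {
    al <- assign_states(tr, alp, m)
    expect_equal(as.vector(al$letters), alp$letters[truth], info = m)
  }
})

test_that("two-state alternating trajectory encodes as an alternating string", {
  alp <- synthetic_alphabet(2)
  co <- array(0, c(4, 4, 3))
  for (f in 1:4) co[f, , ] <- alp$coords[[1 + (f %% 2)]]
  tr <- trajectory(co, toy_topology(4))
  al <- assign_states(tr, alp)
  expect_equal(as.vector(al$letters), c("B", "A", "B", "A"))
})

test_that("rmsd_local_fit equals the exhaustive quaternion superposition oracle", {
  alp <- synthetic_alphabet(25)
  set.seed(8)
  n_fr <- 40
  co <- array(rnorm(n_fr * 4 * 3, sd = 2.5), c(n_fr, 4, 3))
  tr <- trajectory(co, toy_topology(4))
  al <- assign_states(tr, alp, "rmsd_local_fit")
  for (f in seq_len(n_fr)) {
    rm <- vapply(alp$coords, function(cm) horn_rmsd(cm, co[f, , ]), numeric(1))
    expect_equal(al$letters[f, 1], alp$letters[which.min(rm)])
  }
})

test_that("encoding is stateless across frames (concatenation property)", {
  alp <- synthetic_alphabet(4)
  set.seed(9)
  tr1 <- toy_trajectory(7, 3, jitter = 0.4)
  tr2 <- toy_trajectory(7, 2, jitter = 0.4)
  cat_co <- array(0, c(5, 7, 3))
  cat_co[1:3, , ] <- tr1$coords; cat_co[4:5, , ] <- tr2$coords
  both <- trajectory(cat_co, tr1$topology)
  a1 <- assign_states(tr1, alp)$letters
  a2 <- assign_states(tr2, alp)$letters
  ab <- assign_states(both, alp)$letters
  expect_equal(ab, rbind(a1, a2))
})

test_that("alphabet and alignment files round-trip", {
  alp <- synthetic_alphabet(5)
  f <- withr::local_tempfile(fileext = ".json")
  write_alphabet(alp, f)
  alp2 <- read_alphabet(f)
  expect_equal(alp2$letters, alp$letters)
  expect_equal(alp2$coords[[3]], alp$coords[[3]], tolerance = 1e-12)

  ch <- gen_coupled_state_chain(n_fragments = 6, chain = 1:3, n_frames = 20,
                                seed = 2)
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_alignment(ch$alignment, f2)
  back <- read_alignment(f2)
  expect_equal(back$letters, ch$alignment$letters)
  expect_equal(back$fragments$fragment, ch$alignment$fragments$fragment)
})

test_that("shipped synthetic 25-state alphabet file is valid and matches the builder", {
  f <- system.file("extdata", "alphabet_synthetic25.json", package = "allopath")
  alp <- read_alphabet(f)
  expect_equal(alp$letters, LETTERS[1:25])
  ref <- synthetic_alphabet(25)
  expect_equal(alp$coords[[17]], ref$coords[[17]], tolerance = 1e-10)
})
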